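# Independent oracles, deliberately written with scalar logic and string
# manipulation so they share no code path with the package internals.

# SSB7 classification, one substitution at a time.
oracle_classify7 <- function(ref, alt, five, three) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (ref == "C" && !is.na(three) && three == "G") return("CpG>N")
  if (ref == "G" && !is.na(five) && five == "C") return("CpG>N")
  if (ref %in% c("G", "T")) {
    ref <- comp[[ref]]
    alt <- comp[[alt]]
  }
  paste0(ref, ">", alt)
}

# Brute-force site counting: loop over positions x 3 alternates, translate
# both codons with the standard genetic code.
oracle_count_sites <- function(cds, has_stop = TRUE) {
  gcode <- Biostrings::GENETIC_CODE
  L <- nchar(cds)
  L_eff <- L - if (has_stop) 3L else 0L
  na <- ns <- setNames(numeric(7), ssb7_classes())
  for (p in seq_len(L_eff)) {
    ref <- substr(cds, p, p)
    ci <- (p - 1) %/% 3
    cod <- substr(cds, ci * 3 + 1, ci * 3 + 3)
    wi <- (p - 1) %% 3
    five <- if (p == 1) NA_character_ else substr(cds, p - 1, p - 1)
    three <- if (p == L) NA_character_ else substr(cds, p + 1, p + 1)
    aa_ref <- gcode[[cod]]
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      ncod <- cod
      substr(ncod, wi + 1, wi + 1) <- alt
      k <- oracle_classify7(ref, alt, five, three)
      if (gcode[[ncod]] == aa_ref) ns[k] <- ns[k] + 1 / 3
      else na[k] <- na[k] + 1 / 3
    }
  }
  list(na = na, ns = ns)
}

# Benjamini-Hochberg step-up, spelled out.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}

# Two-sided exact binomial p by direct enumeration of point probabilities.
oracle_binom_two_sided <- function(x, size, prob) {
  d <- dbinom(0:size, size, prob)
  min(1, sum(d[d <= d[x + 1] * (1 + 1e-7)]))
}

# Kolmogorov-Smirnov distance to the uniform distribution on (0, 1].
ks_uniform <- function(p) {
  n <- length(p)
  s <- sort(p)
  max(abs(seq_len(n) / n - s), abs((seq_len(n) - 1) / n - s))
}
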