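# Internal helpers: base encoding, error conditions, seeded evaluation.

.BASES <- c("A", "C", "G", "T")
.COMP <- c(4L, 3L, 2L, 1L) # complement in integer codes: A<->T, C<->G

.base_int <- function(x) match(x, .BASES)

# Signal a classed error so callers/tests can match on condition class.
ssb_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ssbdnds_error")))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL means: use the current stream as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Amino-acid lookup by codon index ((b1-1)*16 + (b2-1)*4 + b3, bases ACGT).
# Built lazily from the standard genetic code.
.codon_env <- new.env(parent = emptyenv())

.codon_aa <- function() {
  if (is.null(.codon_env$aa)) {
    gc_tab <- Biostrings::GENETIC_CODE
    codons <- names(gc_tab)
    b <- matrix(.base_int(unlist(strsplit(codons, "", fixed = TRUE))),
                ncol = 3L, byrow = TRUE)
    idx <- (b[, 1L] - 1L) * 16L + (b[, 2L] - 1L) * 4L + b[, 3L]
    aa <- character(64L)
    aa[idx] <- unname(gc_tab)
    .codon_env$aa <- aa
  }
  .codon_env$aa
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

# Merge 1-based closed integer intervals; returns list(start, end) sorted.
.merge_intervals <- function(start, end) {
  if (length(start) == 0L) return(list(start = integer(0), end = integer(0)))
  o <- order(start, end)
  s <- start[o]; e <- end[o]
  cm <- cummax(e)
  new_grp <- c(TRUE, s[-1L] > cm[-length(cm)] + 0L)
  grp <- cumsum(new_grp)
  list(start = s[new_grp],
       end = as.integer(vapply(split(e, grp), max, numeric(1))))
}
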