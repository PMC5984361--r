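# Per-position enumeration of all possible coding changes ("site table") and
# the fractional synonymous / non-synonymous site counts derived from it.
#
# Every counted CDS position contributes three possible alternate bases, each
# worth 1/3 of a site (Nei-Gojobori-style approximate counting), so per
# transcript the class-summed site total equals the counted CDS length. A
# change is synonymous iff the induced codon change preserves the amino acid;
# changes to or from a stop codon are non-synonymous. The terminal stop
# codon is excluded from counting but still supplies flanking context.

# alternates per reference base (integer codes), one column per ref
.ALT3 <- matrix(c(2L, 3L, 4L, # ref A
                  1L, 3L, 4L, # ref C
                  1L, 2L, 4L, # ref G
                  1L, 2L, 3L), nrow = 3L)

# consequence codes used throughout
.CONS_LEVELS <- c("synonymous", "missense", "nonsense", "other")

#' Enumerate all possible coding changes of a transcriptome
#'
#' Builds the full table of (transcript, position, alternate base) triples
#' over all counted CDS positions, with the substitution class and coding
#' consequence of each change. This is the shared backbone for site
#' counting, cohort simulation and region analysis; it is cached on the
#' transcriptome object.
#'
#' @param tx An `ssb_transcriptome`.
#' @param system Class system, `"SSB7"` or `"SSB192"`. The SSB7 columns are
#'   always present; `"SSB192"` adds the 192-class index (boundary positions
#'   without full context are dropped for that system).
#' @return A list with integer vector components `txi` (transcript index),
#'   `pos` (0-based CDS position), `ref`, `alt` (base codes 1..4 for
#'   A,C,G,T), `class7` (1..7), `cons` (1 synonymous, 2 missense,
#'   3 nonsense) and, for SSB192, `class192` (0..191).
#' @export
site_table <- function(tx, system = c("SSB7", "SSB192")) {
  system <- match.arg(system)
  key <- paste0("st_", system)
  cached <- tx$cache[[key]]
  if (!is.null(cached)) return(cached)
  if (length(tx$tx_id) == 0L) {
    ssb_stop("empty transcriptome", "ssb_empty")
  }

  L <- tx$length
  Leff <- .counted_length(tx)
  b <- .base_int(unlist(strsplit(tx$cds, "", fixed = TRUE), use.names = FALSE))
  txi <- rep.int(seq_along(L), L)
  pos <- sequence(L) - 1L
  n <- length(b)

  five <- c(NA_integer_, b[-n])
  five[pos == 0L] <- NA_integer_
  three <- c(b[-1L], NA_integer_)
  three[pos == L[txi] - 1L] <- NA_integer_

  # codon bookkeeping
  g0 <- cumsum(c(0L, L[-length(L)])) # global offset of each transcript
  ci <- pos %/% 3L
  wi <- pos %% 3L
  cbase <- g0[txi] + ci * 3L
  cod <- (b[cbase + 1L] - 1L) * 16L + (b[cbase + 2L] - 1L) * 4L + b[cbase + 3L]
  aa <- .codon_aa()
  aa_ref <- aa[cod]

  keep <- pos < Leff[txi] # exclude terminal stop codon positions
  idx <- which(keep)

  # expand to 3 alternates per kept position (alts consecutive per position)
  reps <- rep(idx, each = 3L)
  altv <- as.vector(.ALT3[, b[idx]])
  powv <- c(16L, 4L, 1L)[wi[reps] + 1L]
  newcod <- cod[reps] + (altv - b[reps]) * powv
  aa_alt <- aa[newcod]

  cons <- ifelse(aa_alt == aa_ref[reps], 1L, ifelse(aa_alt == "*", 3L, 2L))
  class7 <- .class7_int(b[reps], altv, five[reps], three[reps])

  out <- list(txi = txi[reps], pos = pos[reps], ref = b[reps], alt = altv,
              class7 = class7, cons = cons, system = system)
  if (system == "SSB192") {
    ctx_ok <- !is.na(five[reps]) & !is.na(three[reps])
    out <- lapply(out[c("txi", "pos", "ref", "alt", "class7", "cons")],
                  function(v) v[ctx_ok])
    out$class192 <- .class192_int(out$ref, out$alt,
                                  five[reps][ctx_ok], three[reps][ctx_ok])
    out$system <- system
  }
  class(out) <- "ssb_site_table"
  tx$cache[[key]] <- out
  out
}

#' Count synonymous and non-synonymous sites per transcript and class
#'
#' For every counted CDS position and each of its three possible alternate
#' bases, 1/3 of a site is added to the non-synonymous count `Na_k` of the
#' change's class `k` (if the codon change alters the amino acid, including
#' changes to stop) or to the synonymous count `Ns_k` otherwise. Under SSB7
#' the class-summed total `sum(Na + Ns)` equals the counted CDS length
#' exactly.
#'
#' @param tx An `ssb_transcriptome`.
#' @param system `"SSB7"` or `"SSB192"`.
#' @param by `"transcript"` or `"gene"` (rows aggregated by gene identifier).
#' @return An object of class `ssb_site_spectrum`: list with matrices `na`
#'   and `ns` (rows = transcripts or genes, columns = classes), and the
#'   class-system tag.
#' @examples
#' tx <- transcriptome(c(t1 = "ATGGGA"), has_stop = FALSE)
#' sp <- count_sites(tx)
#' rowSums(sp$na) + rowSums(sp$ns) # == 6, the CDS length
#' @export
count_sites <- function(tx, system = c("SSB7", "SSB192"),
                        by = c("transcript", "gene")) {
  system <- match.arg(system)
  by <- match.arg(by)
  st <- site_table(tx, system)
  k <- if (system == "SSB7") st$class7 else st$class192 + 1L
  nk <- if (system == "SSB7") 7L else 192L
  ntx <- length(tx$tx_id)
  key <- (st$txi - 1L) * nk + k
  syn <- st$cons == 1L
  ns <- matrix(tabulate(key[syn], nbins = ntx * nk) / 3,
               nrow = ntx, ncol = nk, byrow = TRUE)
  na <- matrix(tabulate(key[!syn], nbins = ntx * nk) / 3,
               nrow = ntx, ncol = nk, byrow = TRUE)
  cls <- if (system == "SSB7") ssb7_classes() else as.character(0:191)
  dimnames(na) <- dimnames(ns) <- list(tx$tx_id, cls)
  if (by == "gene") {
    na <- rowsum(na, tx$gene_id, reorder = FALSE)
    ns <- rowsum(ns, tx$gene_id, reorder = FALSE)
  }
  structure(list(na = na, ns = ns, system = system, by = by),
            class = "ssb_site_spectrum")
}

#' @export
print.ssb_site_spectrum <- function(x, ...) {
  cat(sprintf("ssb_site_spectrum (%s, by %s): %d rows x %d classes\n",
              x$system, x$by, nrow(x$na), ncol(x$na)))
  cat(sprintf("  total Na = %.1f, total Ns = %.1f\n", sum(x$na), sum(x$ns)))
  invisible(x)
}

# Column sums over all rows: the exome-wide class spectrum.
.spectrum_totals <- function(spectra) {
  list(na = colSums(spectra$na), ns = colSums(spectra$ns))
}
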