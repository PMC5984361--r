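# Immunopeptidome region analysis.
#
# Epitopes are amino-acid intervals on proteins. All epitope intervals are
# fused into one super-epitope; the remaining parts of the same proteins
# (proteins without any epitope are excluded) form the super-non-epitope.
# Amino acid i corresponds to CDS nucleotides [3(i-1), 3i) (0-based
# half-open), so every region mask is codon-aligned. The first two amino
# acids of each protein are excluded from the complement and from null
# placements. Region dN/dS uses the cohort-level correction weights, not
# weights recomputed from the region's own mutations.

#' Read epitope intervals from a BED-like TSV
#'
#' Three tab-separated columns with a header: `protein_id`, `aa_start`,
#' `aa_end` (1-based, closed intervals in amino-acid coordinates).
#'
#' @param path Path to the interval file.
#' @return data.frame with the three columns.
#' @export
read_epitopes <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("protein_id", "aa_start", "aa_end")
  if (!all(need %in% names(df))) {
    ssb_stop("epitope file must have columns protein_id, aa_start, aa_end",
             "ssb_dialect_error")
  }
  df[need]
}

# Per-transcript codon-level cumulated quantities for fast interval sums:
# cna/cns are (n_codons+1) x 7 cumulative site matrices, cn/cs cumulative
# mutation counts (non-silent / silent).
.codon_cumsums <- function(tx, txis, records = NULL) {
  st <- site_table(tx, "SSB7")
  keep <- st$txi %in% txis
  stx <- st$txi[keep]; scod <- st$pos[keep] %/% 3L
  scls <- st$class7[keep]; ssyn <- st$cons[keep] == 1L

  rec_txi <- rec_cod <- integer(0); rec_syn <- logical(0)
  if (!is.null(records) && nrow(records) > 0L) {
    ok <- !is.na(records$consequence) &
      records$consequence %in% c("missense", "nonsense", "synonymous")
    r <- records[ok, , drop = FALSE]
    ri <- .tx_index(tx, r$transcript_id)
    sel <- ri %in% txis
    rec_txi <- ri[sel]; rec_cod <- r$cds_pos[sel] %/% 3L
    rec_syn <- r$consequence[sel] == "synonymous"
  }

  out <- vector("list", length(txis))
  names(out) <- as.character(txis)
  for (j in seq_along(txis)) {
    i <- txis[j]
    ncod <- .counted_length(tx)[i] %/% 3L
    sel <- stx == i
    cod <- scod[sel]; cls <- scls[sel]; syn <- ssyn[sel]
    key <- cod * 7L + cls # 7*cod + class, classes 1..7
    na <- matrix(tabulate(key[!syn], nbins = ncod * 7L) / 3,
                 nrow = ncod, ncol = 7L, byrow = TRUE)
    ns <- matrix(tabulate(key[syn], nbins = ncod * 7L) / 3,
                 nrow = ncod, ncol = 7L, byrow = TRUE)
    msel <- rec_txi == i
    ncnt <- tabulate(rec_cod[msel][!rec_syn[msel]] + 1L, nbins = ncod)
    scnt <- tabulate(rec_cod[msel][rec_syn[msel]] + 1L, nbins = ncod)
    out[[j]] <- list(
      cna = rbind(0, apply(na, 2L, cumsum)),
      cns = rbind(0, apply(ns, 2L, cumsum)),
      cn = c(0L, cumsum(ncnt)),
      cs = c(0L, cumsum(scnt)),
      ncod = ncod
    )
  }
  out
}

# Sum sites and counts over 1-based closed codon intervals of one transcript.
.interval_sums <- function(cum, start, end) {
  na <- colSums(cum$cna[end + 1L, , drop = FALSE]) -
    colSums(cum$cna[start, , drop = FALSE])
  ns <- colSums(cum$cns[end + 1L, , drop = FALSE]) -
    colSums(cum$cns[start, , drop = FALSE])
  n <- sum(cum$cn[end + 1L] - cum$cn[start])
  s <- sum(cum$cs[end + 1L] - cum$cs[start])
  list(na = na, ns = ns, n = n, s = s)
}

#' Fuse epitope intervals into super-epitope and super-non-epitope masks
#'
#' Overlapping intervals are merged per protein; the complement (non-epitope
#' territory of the same proteins, excluding the first `exclude_first_aa`
#' amino acids) forms the super-non-epitope. Proteins without any annotated
#' epitope contribute to neither side.
#'
#' @param epitopes data.frame with `protein_id`, `aa_start`, `aa_end`
#'   (1-based closed; protein identifiers are transcript or gene ids).
#' @param tx An `ssb_transcriptome`.
#' @param exclude_first_aa Number of leading amino acids excluded from the
#'   complement (default 2).
#' @return Object of class `ssb_super_regions`: per-transcript merged codon
#'   intervals for both sides, plus protein lengths and the transcript map.
#' @export
build_super_regions <- function(epitopes, tx, exclude_first_aa = 2L) {
  txi <- .tx_index(tx, epitopes$protein_id)
  if (anyNA(txi)) {
    ssb_stop(sprintf("unknown protein identifier(s): %s",
                     paste(utils::head(unique(
                       epitopes$protein_id[is.na(txi)]), 5L), collapse = ", ")),
             "ssb_unknown_protein")
  }
  aa_len <- .counted_length(tx) %/% 3L
  bad <- epitopes$aa_start < 1L | epitopes$aa_end > aa_len[txi] |
    epitopes$aa_start > epitopes$aa_end
  if (any(bad)) {
    ssb_stop("epitope interval outside protein bounds", "ssb_out_of_bounds")
  }
  txis <- sort(unique(txi))
  epitope <- non_epitope <- vector("list", length(txis))
  names(epitope) <- names(non_epitope) <- as.character(txis)
  for (j in seq_along(txis)) {
    i <- txis[j]
    sel <- txi == i
    ir <- IRanges::reduce(IRanges::IRanges(epitopes$aa_start[sel],
                                           epitopes$aa_end[sel]))
    full <- IRanges::IRanges(exclude_first_aa + 1L, aa_len[i])
    comp <- IRanges::setdiff(full, ir)
    epitope[[j]] <- list(start = IRanges::start(ir), end = IRanges::end(ir))
    non_epitope[[j]] <- list(start = IRanges::start(comp),
                             end = IRanges::end(comp))
  }
  structure(list(epitope = epitope, non_epitope = non_epitope,
                 txis = txis, aa_len = aa_len[txis],
                 exclude_first_aa = as.integer(exclude_first_aa)),
            class = "ssb_super_regions")
}

#' @export
print.ssb_super_regions <- function(x, ...) {
  n_ep <- sum(vapply(x$epitope, function(r) length(r$start), integer(1)))
  aa_ep <- sum(vapply(x$epitope, function(r) sum(r$end - r$start + 1L),
                      integer(1)))
  cat(sprintf("ssb_super_regions: %d proteins, %d fused epitope intervals (%d aa)\n",
              length(x$txis), n_ep, aa_ep))
  invisible(x)
}

# dN/dS of one mask side given per-transcript cumsums and cohort weights.
.mask_dnds <- function(cums, side, w) {
  na <- numeric(7L); ns <- numeric(7L); n <- 0L; s <- 0L
  for (key in names(side)) {
    iv <- side[[key]]
    if (length(iv$start) == 0L) next
    sm <- .interval_sums(cums[[key]], iv$start, iv$end)
    na <- na + sm$na; ns <- ns + sm$ns; n <- n + sm$n; s <- s + sm$s
  }
  na_corr <- sum(w * na); ns_corr <- sum(w * ns)
  dnds <- if (s > 0 && na_corr > 0) (n / na_corr) / (s / ns_corr) else NA_real_
  list(n = n, s = s, na_corr = na_corr, ns_corr = ns_corr, dnds = dnds)
}

#' SSB-corrected dN/dS of a region mask
#'
#' Restricts mutation counts and site totals to the mask and computes dN/dS
#' with the supplied cohort-level correction weights (not recomputed from
#' the region's own mutations), plus the exact binomial neutrality test.
#'
#' @param regions An `ssb_super_regions` object.
#' @param side `"epitope"` or `"non_epitope"`.
#' @param records Annotated mutation records of the cohort.
#' @param tx An `ssb_transcriptome`.
#' @param weights Cohort correction weights (SSB7), e.g. `fit$weights` from
#'   [ssb_dnds()].
#' @return One-row data.frame: n, s, na_corr, ns_corr, dn, ds, dnds, p.
#' @export
region_dnds <- function(regions, side = c("epitope", "non_epitope"),
                        records, tx, weights) {
  side <- match.arg(side)
  msk <- regions[[side]]
  if (sum(vapply(msk, function(r) length(r$start), integer(1))) == 0L) {
    ssb_stop("empty region mask", "ssb_empty")
  }
  cums <- .codon_cumsums(tx, regions$txis, records)
  r <- .mask_dnds(cums, msk, weights)
  if (r$na_corr <= 0 || r$ns_corr <= 0) {
    ssb_stop("degenerate corrected sites in region", "ssb_degenerate_sites")
  }
  out <- data.frame(n = r$n, s = r$s, na_corr = r$na_corr,
                    ns_corr = r$ns_corr,
                    dn = r$n / r$na_corr, ds = r$s / r$ns_corr,
                    dnds = r$dnds)
  out$p <- if (r$n + r$s >= 1L) {
    neutrality_test(r$n, r$s, r$na_corr, r$ns_corr)
  } else {
    NA_real_
  }
  out
}

#' Coordinate-shifting permutation test for epitope selection
#'
#' Shifts each epitope interval, keeping its length and protein, to a start
#' drawn uniformly among placements fully contained in the protein's
#' non-epitope territory (after excluding the first two amino acids), and
#' recomputes the super-region dN/dS per permutation with fixed cohort
#' weights. The one-sided exact P value (toward negative selection) uses
#' the add-one rule: `p = (1 + #[null <= observed]) / (1 + n_perm)`.
#' Intervals with no eligible placement are skipped from the null with a
#' warning. Permutations whose placement yields an undefined ratio (no
#' silent mutation) never count as at-or-below the observation.
#'
#' @param epitopes data.frame with `protein_id`, `aa_start`, `aa_end`.
#' @param tx An `ssb_transcriptome`.
#' @param records Annotated mutation records of the cohort.
#' @param weights Cohort SSB7 correction weights.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional RNG seed (identical seed, identical null).
#' @param exclude_first_aa Leading amino acids excluded from placements.
#' @param placement `"contained"` (default): shifted intervals must lie
#'   fully inside non-epitope territory, so no epitope signal leaks into
#'   the null. `"overlap"`: any placement inside the protein (beyond the
#'   excluded leading residues) touching at least one non-epitope residue
#'   is eligible.
#' @return Object of class `ssb_permutation_test`: list with `p_value`,
#'   `observed` (one-row data.frame from [region_dnds()]), `null` (numeric
#'   vector of permuted dN/dS), `n_perm`, `n_skipped`, `seed`.
#' @export
permutation_test <- function(epitopes, tx, records, weights,
                             n_perm = 1000L, seed = NULL,
                             exclude_first_aa = 2L,
                             placement = c("contained", "overlap")) {
  placement <- match.arg(placement)
  regions <- build_super_regions(epitopes, tx,
                                 exclude_first_aa = exclude_first_aa)
  cums <- .codon_cumsums(tx, regions$txis, records)
  obs <- .mask_dnds(cums, regions$epitope, weights)

  # eligible starts per interval within its protein's non-epitope territory
  iv_tx <- character(0); iv_len <- integer(0); starts_list <- list()
  n_skipped <- 0L
  for (key in names(regions$epitope)) {
    terr <- regions$non_epitope[[key]]
    ep <- regions$epitope[[key]]
    aa_len <- regions$aa_len[match(as.integer(key), regions$txis)]
    for (q in seq_along(ep$start)) {
      len <- ep$end[q] - ep$start[q] + 1L
      ok_starts <- integer(0)
      for (g in seq_along(terr$start)) {
        if (placement == "contained") {
          lo <- terr$start[g]
          hi <- terr$end[g] - len + 1L
        } else {
          lo <- max(exclude_first_aa + 1L, terr$start[g] - len + 1L)
          hi <- min(terr$end[g], aa_len - len + 1L)
        }
        if (hi >= lo) ok_starts <- c(ok_starts, lo:hi)
      }
      ok_starts <- unique(ok_starts)
      if (length(ok_starts) == 0L) {
        n_skipped <- n_skipped + 1L
      } else {
        iv_tx <- c(iv_tx, key)
        iv_len <- c(iv_len, len)
        starts_list <- c(starts_list, list(ok_starts))
      }
    }
  }
  if (length(starts_list) == 0L) {
    ssb_stop("no epitope interval has an eligible null placement",
             "ssb_degenerate")
  }
  if (n_skipped > 0L) {
    warning(sprintf("%d interval(s) without eligible null placement skipped",
                    n_skipped))
  }

  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      st <- vapply(starts_list, function(ok) {
        ok[sample.int(length(ok), 1L)]
      }, integer(1))
      en <- st + iv_len - 1L
      na <- numeric(7L); ns <- numeric(7L); n <- 0L; s <- 0L
      for (key in unique(iv_tx)) {
        sel <- iv_tx == key
        mg <- .merge_intervals(st[sel], en[sel])
        sm <- .interval_sums(cums[[key]], mg$start, mg$end)
        na <- na + sm$na; ns <- ns + sm$ns; n <- n + sm$n; s <- s + sm$s
      }
      na_corr <- sum(weights * na); ns_corr <- sum(weights * ns)
      if (s > 0 && na_corr > 0) (n / na_corr) / (s / ns_corr) else NA_real_
    }, numeric(1))
  })

  p <- (1 + sum(!is.na(null) & null <= obs$dnds)) / (1 + n_perm)
  obs_df <- data.frame(n = obs$n, s = obs$s, na_corr = obs$na_corr,
                       ns_corr = obs$ns_corr, dnds = obs$dnds)
  structure(list(p_value = p, observed = obs_df, null = null,
                 n_perm = as.integer(n_perm), n_skipped = n_skipped,
                 seed = seed),
            class = "ssb_permutation_test")
}

#' @export
print.ssb_permutation_test <- function(x, ...) {
  cat(sprintf("ssb_permutation_test: observed dN/dS = %.4f, p = %.4g (%d permutations)\n",
              x$observed$dnds, x$p_value, x$n_perm))
  invisible(x)
}
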