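# SSB correction and selection inference.
#
# The correction reweights each substitution class k by the fold change
# w_k = observed_freq_k / expected_freq_k, where the expected frequency is
# the class's share of all sites in the transcriptome. Corrected per-gene
# site totals Na' = sum_k w_k Na_k and Ns' = sum_k w_k Ns_k then absorb the
# cohort's mutational signature, so that under neutrality dN = n/Na' and
# dS = s/Ns' estimate the same per-site rate and dN/dS is centred on one.
# Selection is tested per gene with an exact binomial test of the non-silent
# count n among n+s coding mutations against pi = Na'/(Na'+Ns'), under the
# assumption that synonymous somatic mutations are passengers.

#' Expected substitution-class frequencies from site composition
#'
#' The expected frequency of class k is its share of all (synonymous plus
#' non-synonymous) sites across the transcriptome:
#' `(Na_k + Ns_k) / sum_j (Na_j + Ns_j)`.
#'
#' @param spectra An `ssb_site_spectrum` (any row grouping; columns summed).
#' @return Named numeric vector of class frequencies summing to one.
#' @export
expected_frequencies <- function(spectra) {
  tot <- .spectrum_totals(spectra)
  all_sites <- tot$na + tot$ns
  if (sum(all_sites) <= 0) ssb_stop("empty site spectrum", "ssb_empty")
  all_sites / sum(all_sites)
}

#' Observed substitution-class spectrum of a cohort
#'
#' Counts retained coding mutations (synonymous, missense, nonsense) per
#' substitution class and normalises to frequencies.
#'
#' @param records Annotated mutation records.
#' @param system `"SSB7"` or `"SSB192"`.
#' @return list with `counts` and `freq`, both named by class.
#' @export
observed_spectrum <- function(records, system = c("SSB7", "SSB192")) {
  system <- match.arg(system)
  ok <- !is.na(records$consequence) &
    records$consequence %in% c("missense", "nonsense", "synonymous")
  if (system == "SSB7") {
    counts <- table(factor(records$class7[ok], levels = ssb7_classes()))
  } else {
    cl <- records$class192[ok]
    counts <- table(factor(cl[!is.na(cl)], levels = 0:191))
  }
  counts <- stats::setNames(as.integer(counts), names(counts))
  total <- sum(counts)
  freq <- if (total > 0) counts / total else counts * 0
  list(counts = counts, freq = freq, system = system)
}

#' Fold-change correction weights (observed over expected frequencies)
#'
#' `w_k = observed_freq_k / expected_k`; classes with zero observed
#' mutations get weight zero (they contribute no mutations, hence no
#' corrected sites). A warning is emitted when more than two classes are
#' unobserved.
#'
#' @param observed Result of [observed_spectrum()] (or a named frequency
#'   vector).
#' @param expected Named expected-frequency vector from
#'   [expected_frequencies()].
#' @return Named numeric vector of non-negative weights.
#' @export
fold_change_weights <- function(observed, expected) {
  freq <- if (is.list(observed)) observed$freq else observed
  if (sum(freq) <= 0) ssb_stop("no observed mutations", "ssb_no_mutations")
  stopifnot(length(freq) == length(expected))
  w <- ifelse(freq > 0, freq / expected, 0)
  if (sum(freq == 0) > 2L) {
    warning(sprintf("%d substitution classes unobserved; their sites get weight 0",
                    sum(freq == 0)))
  }
  stats::setNames(as.numeric(w), names(expected))
}

#' SSB-corrected site totals per gene
#'
#' `Na' = sum_k w_k Na_k`, `Ns' = sum_k w_k Ns_k`. When every class is
#' observed, the corrected class shares of `w_k (Na_k + Ns_k)` reproduce the
#' observed mutation-class frequencies exactly.
#'
#' @param spectra An `ssb_site_spectrum`.
#' @param w Correction weights from [fold_change_weights()] (length must
#'   match the class system).
#' @return data.frame with `gene_id` (or transcript id), `na_corr`,
#'   `ns_corr`.
#' @export
corrected_sites <- function(spectra, w) {
  if (length(w) != ncol(spectra$na)) {
    ssb_stop("correction weights do not match the spectrum's class system",
             "ssb_system_mismatch")
  }
  data.frame(gene_id = rownames(spectra$na),
             na_corr = as.numeric(spectra$na %*% w),
             ns_corr = as.numeric(spectra$ns %*% w),
             stringsAsFactors = FALSE)
}

#' dN, dS and their ratio from counts and corrected sites
#'
#' `dN = n/Na'`, `dS = s/Ns'`, `dN/dS = dN/dS`. When `s == 0` the ratio is
#' undefined and returned as `NA` (the neutrality P value is still
#' computable).
#'
#' @param n,s Non-silent and silent mutation counts (vectors).
#' @param na_corr,ns_corr Corrected site totals.
#' @return data.frame with columns `dn`, `ds`, `dnds`.
#' @export
gene_dnds <- function(n, s, na_corr, ns_corr) {
  if (any(na_corr <= 0 | ns_corr <= 0)) {
    ssb_stop("corrected site totals must be positive", "ssb_degenerate_sites")
  }
  dn <- n / na_corr
  ds <- s / ns_corr
  dnds <- ifelse(s == 0, NA_real_, dn / ds)
  data.frame(dn = dn, ds = ds, dnds = dnds)
}

#' Exact binomial neutrality test under the passenger-synonymous assumption
#'
#' Tests `n` non-silent mutations among `n + s` coding mutations against a
#' success probability `pi = Na'/(Na' + Ns')`. The two-sided P value sums
#' the probabilities of all outcomes no more probable than the observed one
#' (the standard minimum-likelihood rule).
#'
#' @param n,s Non-silent and silent counts (vectors).
#' @param na_corr,ns_corr Corrected site totals.
#' @return Numeric vector of P values in (0, 1].
#' @export
neutrality_test <- function(n, s, na_corr, ns_corr) {
  size <- n + s
  if (any(size < 1L)) ssb_stop("gene without mutations", "ssb_no_mutations")
  pi0 <- na_corr / (na_corr + ns_corr)
  m <- length(size)
  pi0 <- rep_len(pi0, m)
  p <- numeric(m)
  for (i in seq_len(m)) {
    d <- stats::dbinom(0:size[i], size[i], pi0[i])
    p[i] <- sum(d[d <= d[n[i] + 1L] * (1 + 1e-7)])
  }
  pmin(p, 1)
}

#' Confidence interval for dN/dS on the log-ratio scale
#'
#' Normal approximation on the log ratio:
#' `exp(log(dnds) +/- z * sqrt(1/n + 1/s))`. Undefined (NA) when either
#' count is zero.
#'
#' @param n,s Non-silent and silent counts.
#' @param na_corr,ns_corr Corrected site totals.
#' @param level Coverage level, default 0.95.
#' @return data.frame with `ci_low`, `ci_high`.
#' @export
dnds_confidence_interval <- function(n, s, na_corr, ns_corr, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ok <- n > 0 & s > 0
  est <- (n / na_corr) / (s / ns_corr)
  se <- sqrt(1 / n + 1 / s)
  data.frame(ci_low = ifelse(ok, exp(log(est) - z * se), NA_real_),
             ci_high = ifelse(ok, exp(log(est) + z * se), NA_real_))
}

#' Benjamini-Hochberg FDR correction and selection labels
#'
#' Adds BH-adjusted Q values and labels each gene `positive` (dN/dS above
#' one at `q < q_threshold`), `negative` (below one at `q < q_threshold`) or
#' `neutral`. Genes with `s == 0` (undefined ratio) are labelled by the
#' direction of `dN` versus `dS`, i.e. positive when significant.
#'
#' @param results data.frame with at least columns `p`, `dn`, `ds`.
#' @param q_threshold FDR threshold, default 0.1.
#' @return `results` with added `q` and `label` columns.
#' @export
fdr_classify <- function(results, q_threshold = 0.1) {
  results$q <- stats::p.adjust(results$p, method = "BH")
  direction <- sign(results$dn * 1 - results$ds * 1)
  label <- rep("neutral", nrow(results))
  sig <- !is.na(results$q) & results$q < q_threshold
  label[sig & direction > 0] <- "positive"
  label[sig & direction < 0] <- "negative"
  results$label <- label
  results
}

#' Per-gene SSB-corrected dN/dS over a cohort
#'
#' Runs the full selection pipeline on annotated mutation records: observed
#' class spectrum, fold-change correction weights, corrected per-gene site
#' totals, per-gene counts, dN/dS, the exact binomial neutrality test,
#' BH-FDR correction and selection labels, plus the whole-exome global
#' estimate.
#'
#' @param records Annotated mutation records (see [annotate_consequences()]).
#' @param tx An `ssb_transcriptome`.
#' @param spectra Optional precomputed gene-level `ssb_site_spectrum` (saves
#'   recomputation in simulation loops).
#' @param system `"SSB7"` (default) or `"SSB192"`.
#' @param weights_scope `"cohort"` (default: one observed spectrum for the
#'   whole cohort applied to every gene) or `"gene"` (per-gene observed
#'   frequencies; noisy for sparsely mutated genes).
#' @param q_threshold FDR threshold for the selection labels.
#' @param gene_filters Apply the gene-level filters (site-ratio, blocklist)?
#' @param blocklist Optional gene blocklist.
#' @param max_site_ratio Na/Ns site-ratio cut-off for gene filtering.
#' @param ci Compute 95% confidence intervals?
#' @return An object of class `ssb_dnds_result`: list with `genes` (per-gene
#'   data.frame: gene_id, n, s, na_corr, ns_corr, dn, ds, dnds, ci_low,
#'   ci_high, p, q, label), `global` (one-row data.frame), `weights`,
#'   `observed`, `expected`, `system`.
#' @export
ssb_dnds <- function(records, tx, spectra = NULL,
                     system = c("SSB7", "SSB192"),
                     weights_scope = c("cohort", "gene"),
                     q_threshold = 0.1, gene_filters = TRUE,
                     blocklist = NULL, max_site_ratio = 5, ci = TRUE) {
  system <- match.arg(system)
  weights_scope <- match.arg(weights_scope)
  if (is.null(spectra)) spectra <- count_sites(tx, system, by = "gene")
  stopifnot(spectra$system == system)

  keep <- !is.na(records$consequence) &
    records$consequence %in% c("missense", "nonsense", "synonymous")
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) ssb_stop("no coding mutations", "ssb_no_mutations")
  if (gene_filters) {
    records <- apply_gene_filters(records, spectra, blocklist = blocklist,
                                  max_site_ratio = max_site_ratio)
  }

  expected <- expected_frequencies(spectra)
  obs <- observed_spectrum(records, system)
  w <- fold_change_weights(obs, expected)

  tal <- tally_cohort(records)
  gi <- match(tal$gene_id, rownames(spectra$na))

  if (weights_scope == "cohort") {
    cs <- corrected_sites(spectra, w)
    na_corr <- cs$na_corr[gi]
    ns_corr <- cs$ns_corr[gi]
  } else {
    cls <- if (system == "SSB7") {
      factor(records$class7, levels = ssb7_classes())
    } else {
      factor(records$class192, levels = 0:191)
    }
    cnt <- table(factor(records$gene_id, levels = tal$gene_id), cls)
    gfreq <- cnt / pmax(rowSums(cnt), 1L)
    wmat <- sweep(as.matrix(gfreq), 2L, expected, "/")
    na_corr <- rowSums(spectra$na[gi, , drop = FALSE] * wmat)
    ns_corr <- rowSums(spectra$ns[gi, , drop = FALSE] * wmat)
  }

  ok_sites <- na_corr > 0 & ns_corr > 0
  if (!all(ok_sites)) {
    warning(sprintf("%d gene(s) with degenerate corrected sites excluded",
                    sum(!ok_sites)))
  }
  genes <- data.frame(gene_id = tal$gene_id, n = tal$n, s = tal$s,
                      na_corr = na_corr, ns_corr = ns_corr,
                      stringsAsFactors = FALSE)[ok_sites, , drop = FALSE]
  genes <- cbind(genes, gene_dnds(genes$n, genes$s, genes$na_corr,
                                  genes$ns_corr))
  if (ci) {
    genes <- cbind(genes, dnds_confidence_interval(genes$n, genes$s,
                                                   genes$na_corr,
                                                   genes$ns_corr))
  }
  genes$p <- neutrality_test(genes$n, genes$s, genes$na_corr, genes$ns_corr)
  genes <- fdr_classify(genes, q_threshold = q_threshold)

  glob <- global_dnds(records, tx, spectra = spectra, system = system,
                      weights = w)
  structure(list(genes = genes, global = glob, weights = w,
                 observed = obs, expected = expected, system = system,
                 weights_scope = weights_scope, q_threshold = q_threshold),
            class = "ssb_dnds_result")
}

#' @export
print.ssb_dnds_result <- function(x, ...) {
  cat(sprintf("ssb_dnds_result (%s, %s weights): %d genes tested\n",
              x$system, x$weights_scope, nrow(x$genes)))
  cat(sprintf("  global dN/dS = %.4f (95%% CI %.4f-%.4f)\n",
              x$global$dnds, x$global$ci_low, x$global$ci_high))
  cat(sprintf("  labels at Q < %g: %d positive, %d negative, %d neutral\n",
              x$q_threshold, sum(x$genes$label == "positive"),
              sum(x$genes$label == "negative"),
              sum(x$genes$label == "neutral")))
  invisible(x)
}

#' Global (whole-exome) SSB-corrected dN/dS
#'
#' Treats the whole exome as a single gene: class-summed site spectrum,
#' cohort correction weights, summed mutation counts.
#'
#' @param records Annotated mutation records.
#' @param tx An `ssb_transcriptome`.
#' @param spectra Optional precomputed gene-level spectrum.
#' @param system `"SSB7"` or `"SSB192"`.
#' @param weights Optional precomputed correction weights (defaults to the
#'   cohort fold-change weights of `records`).
#' @return One-row data.frame: n, s, na_corr, ns_corr, dn, ds, dnds, ci_low,
#'   ci_high, p.
#' @export
global_dnds <- function(records, tx, spectra = NULL,
                        system = c("SSB7", "SSB192"), weights = NULL) {
  system <- match.arg(system)
  keep <- !is.na(records$consequence) &
    records$consequence %in% c("missense", "nonsense", "synonymous")
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) ssb_stop("no coding mutations", "ssb_no_mutations")
  if (is.null(spectra)) spectra <- count_sites(tx, system, by = "gene")
  if (is.null(weights)) {
    weights <- fold_change_weights(observed_spectrum(records, system),
                                   expected_frequencies(spectra))
  }
  tot <- .spectrum_totals(spectra)
  na_corr <- sum(weights * tot$na)
  ns_corr <- sum(weights * tot$ns)
  n <- sum(records$consequence != "synonymous")
  s <- sum(records$consequence == "synonymous")
  out <- data.frame(n = n, s = s, na_corr = na_corr, ns_corr = ns_corr)
  out <- cbind(out, gene_dnds(n, s, na_corr, ns_corr))
  out <- cbind(out, dnds_confidence_interval(n, s, na_corr, ns_corr))
  out$p <- neutrality_test(n, s, na_corr, ns_corr)
  out
}

#' Combine cohort-level results into a pan-cancer estimate
#'
#' Weights each cohort's corrected site totals by its share of somatic
#' mutations, `f_t = m_t / sum(m)`, sums the mutation counts, and recomputes
#' dN/dS, the confidence interval and the neutrality test.
#'
#' @param per_cohort data.frame with columns `m` (cohort mutation count,
#'   post-filter), `na_corr`, `ns_corr`, `n`, `s`.
#' @return One-row data.frame as in [global_dnds()].
#' @export
pan_cancer_combine <- function(per_cohort) {
  stopifnot(all(c("m", "na_corr", "ns_corr", "n", "s") %in% names(per_cohort)))
  if (nrow(per_cohort) < 1L || sum(per_cohort$m) <= 0) {
    ssb_stop("no mutations across cohorts", "ssb_no_mutations")
  }
  f <- per_cohort$m / sum(per_cohort$m)
  na_corr <- sum(f * per_cohort$na_corr)
  ns_corr <- sum(f * per_cohort$ns_corr)
  n <- sum(per_cohort$n)
  s <- sum(per_cohort$s)
  out <- data.frame(n = n, s = s, na_corr = na_corr, ns_corr = ns_corr)
  out <- cbind(out, gene_dnds(n, s, na_corr, ns_corr))
  out <- cbind(out, dnds_confidence_interval(n, s, na_corr, ns_corr))
  out$p <- neutrality_test(n, s, na_corr, ns_corr)
  out
}
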