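# Neutral and selection-laden somatic mutation simulation, plus the
# precision/recall benchmark of the full calling pipeline.
#
# Neutral SNVs are drawn in three steps: a substitution class from the
# cohort signature, a (position, alternate) pair uniformly among the
# class's eligible coding changes across the transcriptome (so gene
# composition enters through per-gene eligible-site counts), and the
# consequence read off the codon change. Selection is imposed afterwards:
# in a targeted gene each non-synonymous mutation is retained independently
# with probability min(omega, 1); for omega > 1 additional non-synonymous
# mutations are drawn from the gene's class-weighted eligible sites so that
# the expected non-synonymous count is omega times the neutral expectation.

#' Default simulated 7-class mutational signature
#'
#' A pan-cancer-like substitution spectrum dominated by C>T changes, with a
#' strong CpG>N component. Values are the sampling probabilities of the
#' seven SSB7 classes and sum to one.
#' @return Named numeric vector over [ssb7_classes()].
#' @export
default_signature <- function() {
  stats::setNames(c(0.07, 0.06, 0.14, 0.12, 0.25, 0.09, 0.27),
                  ssb7_classes())
}

#' Generate a toy transcriptome of known codon composition
#'
#' Sequences are built codon-wise: a start codon, a body of codons sampled
#' from the 61 sense codons with probabilities induced by the per-base GC
#' bias (so no internal stop codons can arise), and a terminal stop codon.
#' Lengths are drawn from a log-normal distribution and rounded to whole
#' codons.
#'
#' @param n_genes Number of genes (one transcript each).
#' @param mean_length Median CDS length in nucleotides (log-normal scale
#'   parameter).
#' @param sdlog Log-normal shape parameter of the length distribution.
#' @param gc_bias Probability mass on G or C per base (0.5 = uniform).
#' @param seed Optional RNG seed.
#' @return An `ssb_transcriptome` with transcript ids `TX...` and gene ids
#'   `G...`.
#' @export
make_toy_transcriptome <- function(n_genes, mean_length = 1300,
                                   sdlog = 0.55, gc_bias = 0.5,
                                   seed = NULL) {
  if (n_genes < 0 || gc_bias <= 0 || gc_bias >= 1 || mean_length < 9) {
    ssb_stop("infeasible transcriptome configuration", "ssb_config_error")
  }
  if (n_genes == 0L) {
    return(transcriptome(character(0), tx_id = character(0)))
  }
  with_seed(seed, {
    n_cod <- pmax(30L, as.integer(round(
      stats::rlnorm(n_genes, log(mean_length), sdlog) / 3)))
    # sense-codon sampling probabilities from per-base composition
    pbase <- c(A = (1 - gc_bias) / 2, C = gc_bias / 2,
               G = gc_bias / 2, T = (1 - gc_bias) / 2)
    codons <- apply(expand.grid(.BASES, .BASES, .BASES,
                                stringsAsFactors = FALSE)[, 3:1], 1L,
                    paste, collapse = "")
    pcod <- apply(expand.grid(pbase, pbase, pbase)[, 3:1], 1L, prod)
    sense <- !(codons %in% .STOP_CODONS)
    body_total <- sum(n_cod - 2L)
    body <- sample(codons[sense], body_total, replace = TRUE,
                   prob = pcod[sense] / sum(pcod[sense]))
    stops <- sample(.STOP_CODONS, n_genes, replace = TRUE)
    grp <- rep.int(seq_len(n_genes), n_cod - 2L)
    bodies <- vapply(split(body, grp), paste, character(1), collapse = "")
    cds <- paste0("ATG", bodies, stops)
    transcriptome(cds,
                  tx_id = sprintf("TX%05d", seq_len(n_genes)),
                  gene_id = sprintf("G%05d", seq_len(n_genes)),
                  has_stop = rep(TRUE, n_genes))
  })
}

# Row indices of the SSB7 site table grouped by class, cached.
.class_row_index <- function(tx) {
  cached <- tx$cache$class_rows
  if (!is.null(cached)) return(cached)
  st <- site_table(tx, "SSB7")
  idx <- split(seq_along(st$class7), st$class7)
  out <- vector("list", 7L)
  out[as.integer(names(idx))] <- idx
  for (k in seq_len(7L)) if (is.null(out[[k]])) out[[k]] <- integer(0)
  tx$cache$class_rows <- out
  out
}

# Turn sampled site-table rows into an annotated mutation record data.frame.
.rows_to_records <- function(tx, st, rows, sample_id) {
  txi <- st$txi[rows]
  pos <- st$pos[rows]
  refi <- st$ref[rows]
  alti <- st$alt[rows]
  data.frame(
    sample_id = sample_id,
    transcript_id = tx$tx_id[txi],
    gene_id = tx$gene_id[txi],
    cds_pos = pos,
    ref = .BASES[refi],
    alt = .BASES[alti],
    ref_ok = rep(TRUE, length(rows)),
    consequence = .CONS_LEVELS[st$cons[rows]],
    class7 = ssb7_classes()[st$class7[rows]],
    stringsAsFactors = FALSE
  )
}

#' Simulate a neutral somatic mutation cohort
#'
#' @param tx An `ssb_transcriptome`.
#' @param n_mutations Number of SNVs to draw.
#' @param class_probs Named 7-class signature summing to one (see
#'   [default_signature()]).
#' @param n_samples Number of tumour sample identifiers to spread mutations
#'   over (labels only; does not affect the statistics).
#' @param seed Optional RNG seed; identical seeds give identical cohorts.
#' @return Annotated mutation records (as from [annotate_consequences()]).
#' @export
simulate_neutral <- function(tx, n_mutations, class_probs = default_signature(),
                             n_samples = 100L, seed = NULL) {
  stopifnot(n_mutations >= 0)
  if (abs(sum(class_probs) - 1) > 1e-6 || any(class_probs < 0)) {
    ssb_stop("class probabilities must be non-negative and sum to 1",
             "ssb_config_error")
  }
  st <- site_table(tx, "SSB7")
  by_class <- .class_row_index(tx)
  if (n_mutations == 0L) {
    return(.rows_to_records(tx, st, integer(0), character(0)))
  }
  with_seed(seed, {
    probs <- as.numeric(class_probs)
    empty <- vapply(by_class, length, integer(1)) == 0L & probs > 0
    if (any(empty)) {
      warning(sprintf("class(es) with no eligible positions resampled: %s",
                      paste(ssb7_classes()[empty], collapse = ", ")))
      probs[empty] <- 0
      probs <- probs / sum(probs)
    }
    n_k <- as.integer(stats::rmultinom(1L, n_mutations, probs))
    rows <- unlist(lapply(seq_len(7L), function(k) {
      if (n_k[k] == 0L) return(integer(0))
      by_class[[k]][sample.int(length(by_class[[k]]), n_k[k], replace = TRUE)]
    }), use.names = FALSE)
    rows <- rows[sample.int(length(rows))] # shuffle class blocks
    sample_id <- sprintf("S%04d", sample.int(n_samples, length(rows),
                                             replace = TRUE))
    .rows_to_records(tx, st, rows, sample_id)
  })
}

#' Impose selection on a neutral cohort
#'
#' @param records Neutral annotated mutation records.
#' @param targets Named numeric vector of target dN/dS values (omega) by
#'   gene identifier; genes absent from `targets` stay neutral.
#' @param tx The `ssb_transcriptome` the cohort was simulated on.
#' @param class_probs The signature used for the neutral cohort (needed to
#'   draw extra mutations for omega > 1).
#' @param seed Optional RNG seed.
#' @return `list(records, truth)` where `truth` is a data.frame with
#'   `gene_id`, `omega`, `n_pre` and `n_post` non-synonymous counts.
#' @export
impose_selection <- function(records, targets, tx,
                             class_probs = default_signature(), seed = NULL) {
  if (length(targets) == 0L) {
    return(list(records = records,
                truth = data.frame(gene_id = character(0), omega = numeric(0),
                                   n_pre = integer(0), n_post = integer(0))))
  }
  if (any(targets < 0)) ssb_stop("omega must be >= 0", "ssb_config_error")
  unknown <- !(names(targets) %in% tx$gene_id)
  if (any(unknown)) {
    ssb_stop(sprintf("selection target on unknown gene(s): %s",
                     paste(utils::head(names(targets)[unknown], 5L),
                           collapse = ", ")), "ssb_config_error")
  }
  st <- site_table(tx, "SSB7")
  with_seed(seed, {
    nonsyn <- records$consequence %in% c("missense", "nonsense")
    tgt_idx <- match(records$gene_id, names(targets))
    hit <- which(nonsyn & !is.na(tgt_idx))
    grp <- split(hit, tgt_idx[hit])
    keep <- rep(TRUE, nrow(records))
    extra_rows <- integer(0)
    n_pre <- integer(length(targets))
    n_pre[as.integer(names(grp))] <- lengths(grp)
    n_post <- n_pre
    cand_by_tx <- NULL; row_w <- NULL
    if (any(targets > 1)) {
      cand_all <- which(st$cons != 1L)
      cand_by_tx <- split(cand_all, st$txi[cand_all])
      n_class_rows <- vapply(.class_row_index(tx), length, integer(1))
      row_w <- as.numeric(class_probs) / pmax(n_class_rows, 1L)
    }
    for (g in seq_along(targets)) {
      om <- targets[[g]]
      rows_g <- grp[[as.character(g)]]
      if (om < 1) {
        if (length(rows_g)) {
          keep[rows_g] <- stats::runif(length(rows_g)) < om
          n_post[g] <- sum(keep[rows_g])
        }
      } else if (om > 1) {
        n_extra <- stats::rpois(1L, (om - 1) * n_pre[g])
        if (n_extra > 0L) {
          txi_g <- which(tx$gene_id == names(targets)[g])
          cand <- unlist(cand_by_tx[as.character(txi_g)], use.names = FALSE)
          extra <- cand[sample.int(length(cand), n_extra, replace = TRUE,
                                   prob = row_w[st$class7[cand]])]
          extra_rows <- c(extra_rows, extra)
        }
        n_post[g] <- n_pre[g] + n_extra
      }
    }
    out <- records[keep, , drop = FALSE]
    if (length(extra_rows) > 0L) {
      add <- .rows_to_records(tx, st, extra_rows,
                              sprintf("S%04d", sample.int(1000L,
                                                          length(extra_rows),
                                                          replace = TRUE)))
      out <- rbind(out, add)
    }
    rownames(out) <- NULL
    list(records = out,
         truth = data.frame(gene_id = names(targets),
                            omega = as.numeric(targets),
                            n_pre = n_pre, n_post = n_post,
                            stringsAsFactors = FALSE))
  })
}

#' Draw a benchmark selection panel
#'
#' @param tx An `ssb_transcriptome`.
#' @param n_genes Panel size.
#' @param omegas Values omega is drawn from (default `seq(0.1, 0.9, 0.1)`,
#'   negative selection).
#' @param seed Optional RNG seed.
#' @return Named numeric vector of omega by gene, usable as `targets`.
#' @export
selection_panel <- function(tx, n_genes, omegas = seq(0.1, 0.9, by = 0.1),
                            seed = NULL) {
  genes <- unique(tx$gene_id)
  if (n_genes > length(genes)) {
    ssb_stop("panel larger than the transcriptome", "ssb_config_error")
  }
  with_seed(seed, {
    picked <- sample(genes, n_genes)
    stats::setNames(sample(omegas, n_genes, replace = TRUE), picked)
  })
}

#' Benchmark precision and recall of the selection caller
#'
#' For each dataset size and seed: simulate a neutral cohort, impose the
#' selection panel, round-trip the cohort through the MAF dialect (so the
#' benchmark exercises the full I/O path), run the selection pipeline, and
#' compare `Q < q_threshold` calls against the truth. Recall is
#' TP/(TP+FN), precision TP/(TP+FP), per selection direction.
#'
#' @param tx An `ssb_transcriptome`.
#' @param sizes Integer vector of neutral cohort sizes (numbers of SNVs).
#' @param targets Named omega vector (see [selection_panel()]).
#' @param class_probs Simulated signature.
#' @param q_threshold FDR threshold for calling.
#' @param seeds Integer vector of seeds; results are reported per seed.
#' @param io Round-trip each simulated cohort through a temporary MAF file.
#' @return data.frame with one row per (size, seed, direction):
#'   tp, fp, fn, precision, recall.
#' @export
benchmark_recall <- function(tx, sizes, targets,
                             class_probs = default_signature(),
                             q_threshold = 0.1, seeds = 1L, io = TRUE) {
  spectra <- count_sites(tx, "SSB7", by = "gene")
  rows <- list()
  for (size in sizes) {
    for (seed in seeds) {
      neutral <- simulate_neutral(tx, size, class_probs = class_probs,
                                  seed = seed)
      sel <- impose_selection(neutral, targets, tx,
                              class_probs = class_probs, seed = seed + 1L)
      recs <- sel$records
      if (io) {
        path <- tempfile(fileext = ".maf.tsv")
        on.exit(unlink(path), add = TRUE)
        write_maf(recs, path)
        recs <- annotate_consequences(read_maf(path), tx)
      }
      # simulated cohorts carry no quality annotations by construction
      recs <- suppressWarnings(apply_quality_filters(recs)$records)
      fit <- ssb_dnds(recs, tx, spectra = spectra,
                      q_threshold = q_threshold)
      for (direction in c("negative", "positive")) {
        truth_genes <- sel$truth$gene_id[
          if (direction == "negative") sel$truth$omega < 1
          else sel$truth$omega > 1]
        if (length(truth_genes) == 0L) next
        called <- fit$genes$gene_id[fit$genes$label == direction]
        tp <- sum(called %in% truth_genes)
        fp <- length(called) - tp
        fn <- length(truth_genes) - tp
        rows[[length(rows) + 1L]] <- data.frame(
          size = size, seed = seed, direction = direction,
          tp = tp, fp = fp, fn = fn,
          precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
          recall = tp / (tp + fn), stringsAsFactors = FALSE)
      }
      if (length(targets) == 0L) {
        called_any <- sum(fit$genes$label != "neutral")
        rows[[length(rows) + 1L]] <- data.frame(
          size = size, seed = seed, direction = "none",
          tp = 0L, fp = called_any, fn = 0L,
          precision = NA_real_,
          recall = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
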