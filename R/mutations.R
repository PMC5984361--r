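# MAF-dialect ingestion, CDS-space consequence annotation, and the quality /
# copy-number / gene-level mutation filters.

#' Column-name mapping for MAF-dialect tables
#'
#' Describes how columns of a tab-separated mutation table map onto the
#' fields the pipeline needs. Positions in files are 1-based CDS
#' coordinates; internally they become 0-based. The defaults follow the
#' TCGA MAF naming for the required columns and plain names for the optional
#' quality annotations.
#'
#' @param transcript,gene,position,ref,alt,sample Required column names
#'   (either `transcript` or `gene` must be present in the file).
#' @param vaf,alt_reads,pop_af,segdup,in_repeat,abb,segment_mean Optional
#'   quality-annotation column names; missing columns simply leave the
#'   annotation absent.
#' @return A named list of column mappings.
#' @export
maf_dialect <- function(transcript = "Transcript_ID",
                        gene = "Hugo_Symbol",
                        position = "Start_position",
                        ref = "Reference_Allele",
                        alt = "Tumor_Seq_Allele2",
                        sample = "Tumor_Sample_Barcode",
                        vaf = "VAF",
                        alt_reads = "t_alt_count",
                        pop_af = "pop_AF",
                        segdup = "segdup_score",
                        in_repeat = "in_repeat",
                        abb = "ABB_score",
                        segment_mean = "segment_mean") {
  as.list(environment())
}

#' Read somatic mutations from a MAF-dialect TSV
#'
#' Parses single-nucleotide variants; rows whose alleles are not single
#' A/C/G/T bases (indels, MNVs) are dropped with a message. Optional quality
#' columns named in the dialect are carried along under standard names.
#'
#' @param path Path to a tab-separated mutation table with a header row.
#' @param dialect Column mapping, see [maf_dialect()].
#' @return A data.frame of mutation records with columns `sample_id`,
#'   `transcript_id`, `cds_pos` (0-based), `ref`, `alt` and any optional
#'   annotations present; the number of dropped non-SNV rows is in
#'   `attr(, "n_non_snv")`.
#' @export
read_maf <- function(path, dialect = maf_dialect()) {
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, showProgress = FALSE)
  need <- c("position", "ref", "alt", "sample")
  miss <- vapply(need, function(f) !(dialect[[f]] %in% names(raw)), logical(1))
  tx_col <- if (dialect$transcript %in% names(raw)) dialect$transcript
            else if (dialect$gene %in% names(raw)) dialect$gene
            else NA_character_
  if (any(miss) || is.na(tx_col)) {
    bad <- c(unlist(dialect[need])[miss],
             if (is.na(tx_col)) sprintf("%s/%s", dialect$transcript, dialect$gene))
    ssb_stop(sprintf("missing required MAF column(s): %s",
                     paste(bad, collapse = ", ")), "ssb_dialect_error")
  }
  rec <- data.frame(
    sample_id = as.character(raw[[dialect$sample]]),
    transcript_id = as.character(raw[[tx_col]]),
    cds_pos = as.integer(raw[[dialect$position]]) - 1L,
    ref = toupper(as.character(raw[[dialect$ref]])),
    alt = toupper(as.character(raw[[dialect$alt]])),
    stringsAsFactors = FALSE
  )
  for (f in c("vaf", "alt_reads", "pop_af", "segdup", "abb", "segment_mean")) {
    if (dialect[[f]] %in% names(raw)) rec[[f]] <- as.numeric(raw[[dialect[[f]]]])
  }
  if (dialect$in_repeat %in% names(raw)) {
    rec$in_repeat <- as.logical(raw[[dialect$in_repeat]])
  }
  snv <- rec$ref %in% .BASES & rec$alt %in% .BASES & rec$ref != rec$alt &
    !is.na(rec$cds_pos)
  n_drop <- sum(!snv)
  if (n_drop > 0L) {
    message(sprintf("read_maf: dropped %d non-SNV or unparseable row(s)", n_drop))
  }
  rec <- rec[snv, , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "n_non_snv") <- n_drop
  rec
}

#' Write mutation records as a MAF-dialect TSV
#'
#' @param records Mutation records (as from [read_maf()] or the simulator).
#' @param path Output path.
#' @param dialect Column mapping, see [maf_dialect()].
#' @export
write_maf <- function(records, path, dialect = maf_dialect()) {
  out <- data.frame(records[["sample_id"]], records[["transcript_id"]],
                    records[["cds_pos"]] + 1L, records[["ref"]],
                    records[["alt"]], stringsAsFactors = FALSE)
  names(out) <- unlist(dialect[c("sample", "transcript", "position", "ref", "alt")])
  for (f in c("vaf", "alt_reads", "pop_af", "segdup", "in_repeat", "abb",
              "segment_mean")) {
    if (f %in% names(records)) out[[dialect[[f]]]] <- records[[f]]
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Annotate coding consequences and substitution classes in CDS space
#'
#' Validates each record against its transcript (position in range,
#' reference allele matching the CDS base), derives the consequence
#' (synonymous / missense / nonsense / other) from the codon change, and
#' assigns the SSB7 class (and SSB192 index where full context exists).
#' Stop-retaining changes in a terminal stop codon are synonymous;
#' stop-lost changes are "other" and are discarded downstream.
#'
#' @param records Mutation records data.frame (see [read_maf()]).
#' @param tx An `ssb_transcriptome`.
#' @param drop_unknown Drop records whose transcript is not in `tx` (with a
#'   warning) instead of erroring.
#' @return The records with added columns `gene_id`, `ref_ok`,
#'   `consequence`, `class7`, `class192`.
#' @export
annotate_consequences <- function(records, tx, drop_unknown = TRUE) {
  txi <- .tx_index(tx, records$transcript_id)
  if (anyNA(txi)) {
    if (!drop_unknown) {
      ssb_stop("unknown transcript identifiers in mutation table",
               "ssb_unknown_protein")
    }
    warning(sprintf("dropping %d record(s) with unknown transcript",
                    sum(is.na(txi))))
    records <- records[!is.na(txi), , drop = FALSE]
    txi <- txi[!is.na(txi)]
  }
  n <- nrow(records)
  if (n == 0L) {
    records$gene_id <- character(0); records$ref_ok <- logical(0)
    records$consequence <- character(0)
    records$class7 <- character(0); records$class192 <- integer(0)
    return(records)
  }
  pos <- records$cds_pos
  L <- tx$length[txi]
  if (any(pos < 0L | pos >= L)) {
    ssb_stop("CDS position beyond transcript bounds", "ssb_out_of_bounds")
  }
  seqs <- tx$cds[txi]
  base_at <- substr(seqs, pos + 1L, pos + 1L)
  ref_ok <- base_at == records$ref
  if (!all(ref_ok)) {
    warning(sprintf(
      "%d record(s) with reference allele not matching the CDS (flagged, excluded)",
      sum(!ref_ok)))
  }

  ci <- pos %/% 3L
  cod_str <- substr(seqs, ci * 3L + 1L, ci * 3L + 3L)
  wi <- pos %% 3L
  alt_cod <- cod_str
  substr(alt_cod, wi + 1L, wi + 1L) <- records$alt
  aa <- .codon_aa()
  cod_idx <- function(s) {
    m <- matrix(.base_int(unlist(strsplit(s, "", fixed = TRUE))), nrow = 3L)
    (m[1L, ] - 1L) * 16L + (m[2L, ] - 1L) * 4L + m[3L, ]
  }
  aa_ref <- aa[cod_idx(cod_str)]
  aa_alt <- aa[cod_idx(alt_cod)]
  consequence <- ifelse(aa_ref == aa_alt, "synonymous",
                 ifelse(aa_alt == "*", "nonsense",
                 ifelse(aa_ref == "*", "other", "missense")))
  consequence[!ref_ok] <- NA_character_

  five <- ifelse(pos == 0L, NA_character_, substr(seqs, pos, pos))
  three <- ifelse(pos == L - 1L, NA_character_, substr(seqs, pos + 2L, pos + 2L))
  refi <- .base_int(records$ref); alti <- .base_int(records$alt)
  records$gene_id <- tx$gene_id[txi]
  records$ref_ok <- ref_ok
  records$consequence <- consequence
  records$class7 <- ssb7_classes()[.class7_int(refi, alti, .base_int(five),
                                               .base_int(three))]
  ctx <- !is.na(five) & !is.na(three)
  cl192 <- rep(NA_integer_, n)
  if (any(ctx)) {
    cl192[ctx] <- .class192_int(refi[ctx], alti[ctx],
                                .base_int(five[ctx]), .base_int(three[ctx]))
  }
  records$class192 <- cl192
  records
}

#' Default quality-filter thresholds
#'
#' The six exclusion criteria, in their documented order: (1) VAF below
#' `vaf`; (2) alternate-allele read count below `alt_reads`; (3) population
#' allele frequency at or above `pop_af`; (4) segmental-duplication score
#' above `segdup`; (5) overlap with a simple repeat; (6) allele-balance-bias
#' score at or below `abb`. Inequality strictness follows the printed
#' operators.
#'
#' @param vaf,alt_reads,pop_af,segdup,abb Numeric cut-offs.
#' @return Named list of thresholds.
#' @export
quality_thresholds <- function(vaf = 0.1, alt_reads = 5, pop_af = 0.01,
                               segdup = 0.5, abb = 0.7) {
  as.list(environment())
}

#' Apply the per-mutation quality filters
#'
#' A record is dropped iff it violates at least one criterion; a record
#' lacking the annotation needed by a criterion passes that criterion (the
#' external scores are cohort-specific resources and may be absent). The
#' drop ledger attributes each dropped record to the first criterion it
#' violates, in the documented order 1-6, so input count equals retained
#' plus the ledger sum.
#'
#' @param records Annotated mutation records.
#' @param thresholds See [quality_thresholds()].
#' @return `list(records = retained records, drops = named integer vector)`.
#' @export
apply_quality_filters <- function(records, thresholds = quality_thresholds()) {
  n <- nrow(records)
  get_num <- function(col) {
    if (col %in% names(records)) records[[col]] else rep(NA_real_, n)
  }
  viol <- cbind(
    vaf = get_num("vaf") < thresholds$vaf,
    alt_reads = get_num("alt_reads") < thresholds$alt_reads,
    pop_af = get_num("pop_af") >= thresholds$pop_af,
    segdup = get_num("segdup") > thresholds$segdup,
    in_repeat = if ("in_repeat" %in% names(records)) records$in_repeat
                else rep(NA, n),
    abb = get_num("abb") <= thresholds$abb
  )
  absent <- colSums(is.na(viol)) == n & n > 0L
  if (any(absent)) {
    warning(sprintf("quality annotation absent, criterion passed for all: %s",
                    paste(colnames(viol)[absent], collapse = ", ")))
  }
  viol[is.na(viol)] <- FALSE
  first <- integer(n)
  for (j in rev(seq_len(ncol(viol)))) first[viol[, j]] <- j
  drops <- tabulate(first, nbins = ncol(viol))
  names(drops) <- colnames(viol)
  list(records = records[first == 0L, , drop = FALSE], drops = drops)
}

#' Keep only mutations in diploid copy-number segments
#'
#' Retains records whose copy-number segment mean lies in `[-0.01, 0.01]`
#' (boundaries inclusive). Records without segment information are dropped
#' with a warning.
#'
#' @param records Mutation records carrying a `segment_mean` column, or
#'   joinable to `segment_means`.
#' @param segment_means Optional data.frame with columns `sample_id`,
#'   `transcript_id`, `segment_mean` used to fill missing values.
#' @param lower,upper Diploid band (inclusive).
#' @return The retained records.
#' @export
filter_diploid <- function(records, segment_means = NULL,
                           lower = -0.01, upper = 0.01) {
  sm <- if ("segment_mean" %in% names(records)) records$segment_mean
        else rep(NA_real_, nrow(records))
  if (!is.null(segment_means)) {
    key <- paste(records$sample_id, records$transcript_id, sep = "\r")
    mkey <- paste(segment_means$sample_id, segment_means$transcript_id,
                  sep = "\r")
    m <- match(key, mkey)
    fill <- is.na(sm) & !is.na(m)
    sm[fill] <- segment_means$segment_mean[m[fill]]
  }
  if (anyNA(sm) && nrow(records) > 0L) {
    warning(sprintf("%d record(s) without segment mean dropped", sum(is.na(sm))))
  }
  keep <- !is.na(sm) & sm >= lower & sm <= upper
  records[keep, , drop = FALSE]
}

#' Tally per-gene non-silent and silent mutation counts
#'
#' @param records Annotated mutation records; rows with consequence
#'   `missense`/`nonsense` count as non-silent (`n`), `synonymous` as silent
#'   (`s`); `other` and un-annotatable rows are ignored.
#' @return data.frame with columns `gene_id`, `n`, `s`.
#' @export
tally_cohort <- function(records) {
  ok <- !is.na(records$consequence) &
    records$consequence %in% c("missense", "nonsense", "synonymous")
  r <- records[ok, , drop = FALSE]
  genes <- unique(r$gene_id)
  gi <- match(r$gene_id, genes)
  nonsil <- r$consequence != "synonymous"
  data.frame(
    gene_id = genes,
    n = tabulate(gi[nonsil], nbins = length(genes)),
    s = tabulate(gi[!nonsil], nbins = length(genes)),
    stringsAsFactors = FALSE
  )
}

#' Apply the gene-level filters
#'
#' Removes (a) genes on an external blocklist (known false positives or
#' non-expressed genes), (b) genes whose total non-synonymous to synonymous
#' site ratio Na/Ns exceeds `max_site_ratio`, and (c) genes with zero
#' non-silent and zero silent mutations.
#'
#' @param records Annotated mutation records.
#' @param spectra Gene-level `ssb_site_spectrum` covering every gene present.
#' @param blocklist Character vector of gene identifiers to drop.
#' @param max_site_ratio Maximum allowed Na/Ns site ratio (default 5).
#' @return Filtered records; removed genes with reasons in
#'   `attr(, "removed_genes")`.
#' @export
apply_gene_filters <- function(records, spectra, blocklist = NULL,
                               max_site_ratio = 5) {
  tal <- tally_cohort(records)
  silent_only <- setdiff(unique(records$gene_id), tal$gene_id)
  if (length(silent_only) > 0L) {
    tal <- rbind(tal, data.frame(gene_id = silent_only, n = 0L, s = 0L,
                                 stringsAsFactors = FALSE))
  }
  m <- match(tal$gene_id, rownames(spectra$na))
  if (anyNA(m)) {
    ssb_stop(sprintf("no site spectrum for gene(s): %s",
                     paste(utils::head(tal$gene_id[is.na(m)], 5L),
                           collapse = ", ")), "ssb_missing_spectrum")
  }
  ratio <- rowSums(spectra$na)[m] / rowSums(spectra$ns)[m]
  reason <- rep(NA_character_, nrow(tal))
  reason[tal$n == 0L & tal$s == 0L] <- "no_coding_mutations"
  reason[ratio > max_site_ratio] <- "site_ratio"
  reason[tal$gene_id %in% blocklist] <- "blocklist"
  removed <- data.frame(gene_id = tal$gene_id[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  keep_genes <- tal$gene_id[is.na(reason)]
  out <- records[records$gene_id %in% keep_genes, , drop = FALSE]
  attr(out, "removed_genes") <- removed
  out
}
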