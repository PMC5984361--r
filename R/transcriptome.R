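#' Build a transcript model set
#'
#' A transcriptome holds one coding sequence (CDS) per transcript together
#' with a transcript-to-gene map. Sequences must be in-frame (length divisible
#' by three), restricted to the A/C/G/T alphabet, and free of internal stop
#' codons when a terminal stop codon is declared. The terminal stop codon, if
#' present, is excluded from site counting but still provides sequence context
#' for its neighbours.
#'
#' @param cds Named character vector of CDS sequences (A/C/G/T only); names
#'   are transcript identifiers unless `tx_id` is given.
#' @param tx_id Character vector of transcript identifiers.
#' @param gene_id Character vector of gene identifiers, parallel to `tx_id`.
#'   Defaults to the transcript identifiers (one transcript per gene).
#' @param has_stop Logical vector: does the CDS end in a stop codon? If
#'   `NULL`, detected from the terminal codon (TAA/TAG/TGA).
#' @return An object of class `ssb_transcriptome`.
#' @export
transcriptome <- function(cds, tx_id = names(cds), gene_id = tx_id,
                          has_stop = NULL) {
  force(tx_id)
  cds <- toupper(as.character(cds))
  if (length(cds) > 0L && (is.null(tx_id) || anyNA(tx_id))) {
    ssb_stop("transcript identifiers are required", "ssb_config_error")
  }
  tx_id <- as.character(tx_id)
  gene_id <- as.character(gene_id)
  stopifnot(length(tx_id) == length(cds), length(gene_id) == length(cds))
  if (anyDuplicated(tx_id)) {
    ssb_stop("duplicated transcript identifiers", "ssb_config_error")
  }

  bad_alpha <- grepl("[^ACGT]", cds)
  if (any(bad_alpha)) {
    ssb_stop(sprintf("non-ACGT characters in CDS of: %s",
                     paste(utils::head(tx_id[bad_alpha], 5L), collapse = ", ")),
             "ssb_invalid_base")
  }
  len <- nchar(cds)
  if (any(len == 0L)) {
    ssb_stop("empty CDS", "ssb_empty")
  }
  bad_len <- len %% 3L != 0L
  if (any(bad_len)) {
    ssb_stop(sprintf("CDS length not divisible by 3 for: %s",
                     paste(utils::head(tx_id[bad_len], 5L), collapse = ", ")),
             "ssb_invalid_frame")
  }
  last_codon <- substr(cds, len - 2L, len)
  if (is.null(has_stop)) {
    has_stop <- last_codon %in% .STOP_CODONS
  }
  has_stop <- rep_len(as.logical(has_stop), length(cds))

  # reject internal stop codons for transcripts carrying a terminal stop
  if (any(has_stop)) {
    n_cod <- len %/% 3L
    check_end <- n_cod - 1L
    aa <- .codon_aa()
    for (i in which(has_stop)) {
      if (check_end[i] < 1L) next
      b <- .base_int(strsplit(substr(cds[i], 1L, 3L * check_end[i]), "",
                              fixed = TRUE)[[1L]])
      cod <- (b[c(TRUE, FALSE, FALSE)] - 1L) * 16L +
        (b[c(FALSE, TRUE, FALSE)] - 1L) * 4L + b[c(FALSE, FALSE, TRUE)]
      if (any(aa[cod] == "*")) {
        ssb_stop(sprintf("internal stop codon in %s", tx_id[i]),
                 "ssb_internal_stop")
      }
    }
  }

  obj <- list(cds = unname(cds), tx_id = tx_id, gene_id = gene_id,
              has_stop = has_stop, length = unname(len),
              cache = new.env(parent = emptyenv()))
  class(obj) <- "ssb_transcriptome"
  obj
}

#' Read coding sequences from a FASTA file
#'
#' Each FASTA record is one transcript CDS; the header (first whitespace
#' token) is the transcript identifier. An optional two-column tab-separated
#' file maps transcript to gene identifiers.
#'
#' @param path Path to a FASTA file of CDS sequences.
#' @param tx2gene Optional path to a headerless two-column TSV
#'   (transcript_id, gene_id).
#' @return An `ssb_transcriptome`.
#' @export
read_cds_fasta <- function(path, tx2gene = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  cds <- as.character(seqs)
  tx_id <- sub("\\s.*$", "", names(seqs))
  gene_id <- tx_id
  if (!is.null(tx2gene)) {
    map <- data.table::fread(tx2gene, header = FALSE, sep = "\t",
                             col.names = c("transcript_id", "gene_id"),
                             data.table = FALSE)
    m <- match(tx_id, map$transcript_id)
    gene_id <- ifelse(is.na(m), tx_id, map$gene_id[m])
  }
  transcriptome(cds, tx_id = tx_id, gene_id = gene_id)
}

#' @export
print.ssb_transcriptome <- function(x, ...) {
  cat(sprintf("ssb_transcriptome: %d transcripts, %d genes, %.0f nt total\n",
              length(x$tx_id), length(unique(x$gene_id)), sum(x$length)))
  cat(sprintf("  terminal stop codon on %d transcripts\n", sum(x$has_stop)))
  invisible(x)
}

#' Number of transcripts in a transcriptome
#' @param x An `ssb_transcriptome`.
#' @export
length.ssb_transcriptome <- function(x) length(x$tx_id)

# Resolve transcript-or-gene identifiers to transcript indices (NA if unknown).
.tx_index <- function(tx, ids) {
  i <- match(ids, tx$tx_id)
  miss <- is.na(i)
  if (any(miss)) i[miss] <- match(ids[miss], tx$gene_id)
  i
}

# Coding length used for site counting (terminal stop excluded).
.counted_length <- function(tx) tx$length - ifelse(tx$has_stop, 3L, 0L)
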