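test_that("read_maf parses SNVs and drops indels with a count", {
  df <- make_records(
    sample_id = c("S1", "S1", "S2"),
    transcript_id = rep(fix_tx$tx_id[1], 3),
    cds_pos = c(3L, 4L, 5L),
    ref = c(substr(fix_tx$cds[1], 4, 4), "-", substr(fix_tx$cds[1], 6, 6)),
    alt = c("A", "T", "A")
  )
  df$ref[1] <- setdiff(c("A", "C"), df$alt[1])[1] # ensure ref != alt
  path <- tempfile(fileext = ".tsv")
  out <- data.frame(Tumor_Sample_Barcode = df$sample_id,
                    Transcript_ID = df$transcript_id,
                    Start_position = df$cds_pos + 1L,
                    Reference_Allele = df$ref, Tumor_Seq_Allele2 = df$alt)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(rec <- read_maf(path), "non-SNV")
  expect_lte(nrow(rec), 2L)
  expect_equal(attr(rec, "n_non_snv") + nrow(rec), 3L)
})

test_that("read_maf handles empty tables and bad headers", {
  path <- tempfile(fileext = ".tsv")
  writeLines(paste("Tumor_Sample_Barcode", "Transcript_ID", "Start_position",
                   "Reference_Allele", "Tumor_Seq_Allele2", sep = "\t"), path)
  expect_equal(nrow(read_maf(path)), 0L)
  path2 <- tempfile(fileext = ".tsv")
  writeLines("a\tb\tc", path2)
  expect_error(read_maf(path2), class = "ssb_dialect_error")
})

test_that("MAF round trip preserves records", {
  recs <- fix_records[1:50, c("sample_id", "transcript_id", "cds_pos",
                              "ref", "alt")]
  path <- write_toy_maf(recs)
  back <- read_maf(path)
  expect_equal(back[names(recs)], recs, ignore_attr = TRUE)
})

test_that("consequences are derived from the codon change", {
  tx <- transcriptome(c(t1 = "ATGGGA", t2 = "ATGTGG"),
                      has_stop = c(FALSE, FALSE))
  recs <- make_records(
    sample_id = "S1",
    transcript_id = c("t1", "t2", "t1"),
    cds_pos = c(5L, 5L, 3L),
    ref = c("A", "G", "G"),
    alt = c("G", "A", "A")
  )
  ann <- annotate_consequences(recs, tx)
  # GGA->GGG silent; TGG->TGA stop gained (counted non-silent); GGA->AGA missense
  expect_equal(ann$consequence, c("synonymous", "nonsense", "missense"))
  expect_true(all(ann$ref_ok))
})

test_that("reference mismatches are flagged and out-of-bounds rejected", {
  tx <- transcriptome(c(t1 = "ATGGGA"), has_stop = FALSE)
  bad_ref <- make_records(sample_id = "S1", transcript_id = "t1",
                          cds_pos = 3L, ref = "C", alt = "A")
  expect_warning(ann <- annotate_consequences(bad_ref, tx), "reference allele")
  expect_false(ann$ref_ok)
  expect_true(is.na(ann$consequence))
  oob <- make_records(sample_id = "S1", transcript_id = "t1",
                      cds_pos = 6L, ref = "A", alt = "C")
  expect_error(annotate_consequences(oob, tx), class = "ssb_out_of_bounds")
})

test_that("annotation is re-derivable (idempotent on retained records)", {
  ann <- annotate_consequences(
    fix_records[1:200, c("sample_id", "transcript_id", "cds_pos", "ref", "alt")],
    fix_tx)
  again <- annotate_consequences(ann, fix_tx)
  expect_equal(again$consequence, ann$consequence)
  expect_equal(again$class7, ann$class7)
})

test_that("quality filters use the printed inequalities and ledger drops", {
  base <- make_records(sample_id = "S", transcript_id = "t", cds_pos = 0L,
                       ref = "A", alt = "G")
  recs <- base[rep(1, 6), ]
  recs$vaf <- c(0.05, NA, NA, NA, NA, NA)
  recs$alt_reads <- c(NA, 4, NA, NA, NA, NA)
  recs$pop_af <- c(NA, NA, 0.01, NA, NA, NA)
  recs$segdup <- c(NA, NA, NA, 0.6, NA, NA)
  recs$in_repeat <- c(NA, NA, NA, NA, TRUE, NA)
  recs$abb <- c(NA, NA, NA, NA, NA, 0.7)
  flt <- apply_quality_filters(recs)
  expect_equal(nrow(flt$records), 0L)
  expect_equal(unname(flt$drops), rep(1L, 6))
  # boundaries: VAF exactly 0.1 retained (strict <), ABB exactly 0.7 dropped (<=)
  edge <- base[rep(1, 2), ]
  edge$vaf <- c(0.1, NA)
  edge$abb <- c(NA, 0.7)
  flt2 <- suppressWarnings(apply_quality_filters(edge))
  expect_equal(nrow(flt2$records), 1L)
  expect_equal(flt2$records$vaf, 0.1)
})

test_that("quality filtering is idempotent and conserves the ledger", {
  recs <- fix_records[1:300, ]
  recs$vaf <- runif(300, 0, 0.3)
  recs$abb <- runif(300)
  flt1 <- suppressWarnings(apply_quality_filters(recs))
  expect_equal(nrow(recs), nrow(flt1$records) + sum(flt1$drops))
  flt2 <- suppressWarnings(apply_quality_filters(flt1$records))
  expect_equal(flt2$records, flt1$records, ignore_attr = TRUE)
  expect_equal(sum(flt2$drops), 0L)
})

test_that("a record violating several criteria is ledgered once, first wins", {
  rec <- make_records(sample_id = "S", transcript_id = "t", cds_pos = 0L,
                      ref = "A", alt = "G", vaf = 0.01, abb = 0.1)
  flt <- suppressWarnings(apply_quality_filters(rec))
  expect_equal(unname(flt$drops["vaf"]), 1L)
  expect_equal(unname(flt$drops["abb"]), 0L)
})

test_that("missing quality columns pass with a warning", {
  rec <- make_records(sample_id = "S", transcript_id = "t", cds_pos = 0L,
                      ref = "A", alt = "G")
  expect_warning(flt <- apply_quality_filters(rec), "absent")
  expect_equal(nrow(flt$records), 1L)
})

test_that("diploid filter keeps the closed segment-mean band", {
  recs <- make_records(sample_id = "S", transcript_id = "t",
                       cds_pos = 0L, ref = "A", alt = "G")[rep(1, 4), ]
  recs$segment_mean <- c(0, 0.02, -0.01, NA)
  expect_warning(kept <- filter_diploid(recs), "without segment mean")
  expect_equal(kept$segment_mean, c(0, -0.01))
  # join from a side table
  recs2 <- recs[4, ]
  recs2$segment_mean <- NULL
  sm <- data.frame(sample_id = "S", transcript_id = "t", segment_mean = 0.005)
  expect_equal(nrow(filter_diploid(recs2, sm)), 1L)
})

test_that("gene filters drop site-ratio offenders and mutationless genes", {
  # two fake genes with controlled spectra
  na <- matrix(c(600, rep(0, 6), 300, rep(0, 6)), nrow = 2, byrow = TRUE,
               dimnames = list(c("gA", "gB"), ssb7_classes()))
  ns <- matrix(c(100, rep(0, 6), 100, rep(0, 6)), nrow = 2, byrow = TRUE,
               dimnames = list(c("gA", "gB"), ssb7_classes()))
  spectra <- structure(list(na = na, ns = ns, system = "SSB7", by = "gene"),
                       class = "ssb_site_spectrum")
  recs <- make_records(
    sample_id = "S", transcript_id = c("gA", "gB", "gB"), cds_pos = 0L,
    ref = "A", alt = "G", gene_id = c("gA", "gB", "gB"),
    consequence = c("missense", "synonymous", "missense"), class7 = "A>G")
  out <- apply_gene_filters(recs, spectra)
  # gA has Na/Ns = 6 > 5: removed; gB retained
  expect_equal(unique(out$gene_id), "gB")
  expect_equal(attr(out, "removed_genes")$reason, "site_ratio")
  # blocklist wins
  out2 <- apply_gene_filters(recs, spectra, blocklist = "gB")
  expect_false("gB" %in% out2$gene_id)
  # gene with only "other" consequences counts as mutationless
  recs3 <- recs
  recs3$consequence <- c("missense", "other", "other")
  out3 <- apply_gene_filters(recs3, spectra)
  expect_true("no_coding_mutations" %in% attr(out3, "removed_genes")$reason)
  # missing spectrum errors
  recs4 <- recs
  recs4$gene_id[1] <- "gC"
  expect_error(apply_gene_filters(recs4, spectra),
               class = "ssb_missing_spectrum")
})
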