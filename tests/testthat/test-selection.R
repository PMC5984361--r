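test_that("expected frequencies are site shares", {
  na <- matrix(c(200, 50), 1, 2, dimnames = list("g", c("k1", "k2")))
  ns <- matrix(c(100, 50), 1, 2, dimnames = list("g", c("k1", "k2")))
  sp <- structure(list(na = na, ns = ns, system = "SSB7", by = "gene"),
                  class = "ssb_site_spectrum")
  expect_equal(unname(expected_frequencies(sp)), c(0.75, 0.25))
  # degenerate single class
  sp1 <- structure(list(na = na[, 1, drop = FALSE], ns = ns[, 1, drop = FALSE],
                        system = "SSB7", by = "gene"),
                   class = "ssb_site_spectrum")
  expect_equal(unname(expected_frequencies(sp1)), 1)
})

test_that("fold-change weights divide observed by expected", {
  w <- fold_change_weights(c(k1 = 0.5, k2 = 0.5), c(k1 = 0.75, k2 = 0.25))
  expect_equal(unname(w), c(2 / 3, 2))
  # observed == expected gives unit weights
  w1 <- fold_change_weights(c(k1 = 0.75, k2 = 0.25), c(k1 = 0.75, k2 = 0.25))
  expect_equal(unname(w1), c(1, 1))
  # unobserved class gets weight zero
  w0 <- fold_change_weights(c(k1 = 1, k2 = 0), c(k1 = 0.75, k2 = 0.25))
  expect_equal(unname(w0[2]), 0)
  expect_error(fold_change_weights(c(k1 = 0, k2 = 0), c(k1 = .5, k2 = .5)),
               class = "ssb_no_mutations")
})

test_that("corrected sites follow the two-class worked example", {
  na <- matrix(c(225, 75), 1, 2, dimnames = list("g", c("k1", "k2")))
  ns <- matrix(c(75, 25), 1, 2, dimnames = list("g", c("k1", "k2")))
  sp <- structure(list(na = na, ns = ns, system = "SSB7", by = "gene"),
                  class = "ssb_site_spectrum")
  cs <- corrected_sites(sp, c(2 / 3, 2))
  expect_equal(cs$na_corr, 300)
  expect_equal(cs$ns_corr, 100)
  # identity weights leave totals unchanged
  cs1 <- corrected_sites(sp, c(1, 1))
  expect_equal(cs1$na_corr, 300)
  expect_equal(cs1$ns_corr, 100)
  expect_error(corrected_sites(sp, rep(1, 7)), class = "ssb_system_mismatch")
})

test_that("corrected class shares reproduce observed frequencies", {
  # the defining reweighting property, on random spectra
  set.seed(5)
  for (rep in 1:50) {
    na_k <- runif(7, 10, 300)
    ns_k <- runif(7, 10, 300)
    tot <- na_k + ns_k
    expected <- tot / sum(tot)
    obs_freq <- as.numeric(rmultinom(1, 500, runif(7, .5, 2) * expected))
    obs_freq <- obs_freq / sum(obs_freq)
    w <- obs_freq / expected
    shares <- (w * tot) / sum(w * tot)
    expect_equal(shares, obs_freq, tolerance = 1e-12)
  }
})

test_that("gene dN/dS handles the printed count examples", {
  r <- gene_dnds(2, 1, 100, 50)
  expect_equal(r$dn, 0.02)
  expect_equal(r$ds, 0.02)
  expect_equal(r$dnds, 1)
  expect_equal(gene_dnds(0, 5, 100, 50)$dnds, 0)
  expect_true(is.na(gene_dnds(4, 0, 100, 50)$dnds))
  expect_error(gene_dnds(1, 1, 0, 50), class = "ssb_degenerate_sites")
})

test_that("neutrality test equals enumeration and the stats oracle", {
  # symmetric null: most probable outcome observed -> p = 1
  expect_equal(neutrality_test(5, 5, 100, 100), 1, tolerance = 1e-12)
  # one-tailed boundary case: n = 0, s = 10, Na' = 2 Ns'
  p <- neutrality_test(0, 10, 200, 100)
  d <- dbinom(0:10, 10, 2 / 3)
  expect_equal(p, sum(d[d <= d[1] * (1 + 1e-7)]))
  expect_equal(d[1], (1 / 3)^10)
  # random cases against binom.test and the enumeration oracle
  set.seed(3)
  for (i in 1:25) {
    size <- sample(1:80, 1)
    n <- sample(0:size, 1)
    nac <- runif(1, 50, 500)
    nsc <- runif(1, 50, 500)
    p1 <- neutrality_test(n, size - n, nac, nsc)
    p2 <- binom.test(n, size, nac / (nac + nsc))$p.value
    p3 <- oracle_binom_two_sided(n, size, nac / (nac + nsc))
    expect_equal(p1, p2, tolerance = 1e-9)
    expect_equal(p1, p3, tolerance = 1e-12)
  }
})

test_that("neutral per-gene p values are approximately uniform", {
  # simulated passenger-only genes; the exact test is discrete, so the
  # property is assessed in the well-populated regime where the point
  # masses are small (the binomial mode mass ~ 1/sqrt(2*pi*m*p*(1-p))
  # bounds the achievable KS distance from below)
  set.seed(11)
  n_genes <- 5000
  nac <- runif(n_genes, 500, 2000)
  nsc <- nac / runif(n_genes, 1.5, 3.5)
  pi0 <- nac / (nac + nsc)
  m <- rpois(n_genes, 400)
  x <- rbinom(n_genes, m, pi0)
  p <- neutrality_test(x, m - x, nac, nsc)
  expect_lt(ks_uniform(p), 0.05)
})

test_that("BH classification reproduces the published gene labels", {
  res <- data.frame(
    p = c(1e-9, 2e-4, 0.5),
    dn = c(25.681, 0.043, 1) * 0.01, ds = c(0.01, 0.01, 0.01),
    dnds = c(25.681, 0.043, 1))
  out <- fdr_classify(res, q_threshold = 0.1)
  expect_equal(out$label, c("positive", "negative", "neutral"))
  # all p == 1 -> everything neutral
  res1 <- data.frame(p = rep(1, 4), dn = c(2, 0.5, 1, 3), ds = rep(1, 4),
                     dnds = c(2, 0.5, 1, 3))
  expect_true(all(fdr_classify(res1)$label == "neutral"))
})

test_that("BH q values match the brute-force step-up oracle", {
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    res <- data.frame(p = p, dn = 1, ds = 1, dnds = 1)
    expect_equal(fdr_classify(res)$q, oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("confidence interval matches the closed form and shrinks with counts", {
  ci <- dnds_confidence_interval(100, 100, 500, 500)
  z <- qnorm(0.975)
  expect_equal(ci$ci_low, exp(-z * sqrt(0.02)))
  expect_equal(ci$ci_high, exp(z * sqrt(0.02)))
  widths <- sapply(c(1, 2, 4, 8), function(f) {
    ci <- dnds_confidence_interval(100 * f, 100 * f, 500 * f, 500 * f)
    log(ci$ci_high) - log(ci$ci_low)
  })
  expect_true(all(diff(widths) < 0))
  expect_true(is.na(dnds_confidence_interval(0, 5, 10, 10)$ci_low))
})

test_that("dnds is monotone in n for fixed sites and s", {
  d <- sapply(0:20, function(n) gene_dnds(n, 5, 300, 100)$dnds)
  expect_true(all(diff(d) > 0))
})

test_that("global dN/dS of a one-gene cohort equals the gene result", {
  one_tx <- transcriptome(fix_tx$cds[1], tx_id = fix_tx$tx_id[1],
                          gene_id = fix_tx$gene_id[1],
                          has_stop = fix_tx$has_stop[1])
  recs <- fix_records[fix_records$transcript_id == fix_tx$tx_id[1], ]
  fit <- ssb_dnds(recs, one_tx, gene_filters = FALSE)
  expect_equal(fit$genes$dnds, fit$global$dnds, tolerance = 1e-12)
  expect_equal(fit$genes$p, fit$global$p, tolerance = 1e-12)
})

test_that("global dN/dS is invariant under duplicating every mutation", {
  recs <- fix_records
  fit1 <- ssb_dnds(recs, fix_tx, spectra = fix_spectra)
  fit2 <- ssb_dnds(rbind(recs, recs), fix_tx, spectra = fix_spectra)
  expect_equal(fit2$global$dnds, fit1$global$dnds, tolerance = 1e-9)
})

test_that("pan-cancer combination weights sites by mutation share", {
  pc <- data.frame(m = c(1000, 3000), na_corr = c(100, 200),
                   ns_corr = c(50, 60), n = c(30, 80), s = c(20, 30))
  out <- pan_cancer_combine(pc)
  expect_equal(out$na_corr, 0.25 * 100 + 0.75 * 200)
  expect_equal(out$ns_corr, 0.25 * 50 + 0.75 * 60)
  expect_equal(out$n, 110)
  # single cohort is the identity
  one <- pan_cancer_combine(pc[1, ])
  expect_equal(one$na_corr, 100)
  expect_equal(one$dnds, (30 / 100) / (20 / 50))
  # identical cohorts reproduce the common result
  same <- pan_cancer_combine(pc[c(1, 1), ])
  expect_equal(same$na_corr, 100)
  expect_equal(same$dnds, one$dnds)
  expect_error(pan_cancer_combine(pc[0, ]), class = "ssb_no_mutations")
})

test_that("per-gene weight scope runs and matches cohort scope on a uniform cohort", {
  fit_c <- ssb_dnds(fix_records, fix_tx, spectra = fix_spectra)
  fit_g <- ssb_dnds(fix_records, fix_tx, spectra = fix_spectra,
                    weights_scope = "gene")
  expect_equal(sort(fit_g$genes$gene_id), sort(fit_c$genes$gene_id))
  expect_true(all(fit_g$genes$na_corr >= 0))
})
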