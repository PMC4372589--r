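test_that("Audic-Claverie p matches frozen exact-rational values to 1e-9", {
  for (i in seq_len(nrow(ac_exact_cases))) {
    cs <- ac_exact_cases[i, ]
    got <- audic_claverie_p(cs$x, cs$y, cs$N1, cs$N2)
    expect_equal(got, cs$p, tolerance = 1e-9,
                 label = sprintf("p(x=%d,y=%d,N1=%g,N2=%g)",
                                 cs$x, cs$y, cs$N1, cs$N2))
  }
})

test_that("Audic-Claverie p agrees with the negative-binomial oracle on a grid", {
  set.seed(1)
  grid <- expand.grid(x = c(0, 1, 7, 40, 100), y = c(0, 3, 25, 100),
                      N1 = c(1e4, 1e6), N2 = c(1e4, 1e7))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_equal(audic_claverie_p(g$x, g$y, g$N1, g$N2),
                 ac_oracle(g$x, g$y, g$N1, g$N2), tolerance = 1e-9)
  }
})

test_that("Audic-Claverie p is orientation-stable and unimodal around the scaled mode", {
  # conditioning on the first count makes the test orientation-asymmetric;
  # at equal library sizes the two orientations agree within a factor 2
  # (each tail shifts by one binomial trial), never more
  set.seed(7)
  for (i in 1:100) {
    x <- sample(0:80, 1); y <- sample(0:80, 1)
    N <- sample(c(1e4, 1e5, 1e6), 1)
    r <- audic_claverie_p(x, y, N, N) / audic_claverie_p(y, x, N, N)
    expect_gte(r, 0.5 - 1e-9)
    expect_lte(r, 2 + 1e-9)
  }
  # p decreases as y moves away from x * N2/N1
  x <- 20; N1 <- 1e5; N2 <- 2e5
  mode <- x * N2 / N1
  ys <- c(mode, mode + c(5, 15, 40), mode - c(5, 15, 39))
  ps <- audic_claverie_p(x, ys, N1, N2)
  expect_true(all(diff(ps[1:4]) < 0))
  expect_true(all(diff(ps[c(1, 5, 6, 7)]) < 0))
  expect_error(audic_claverie_p(-1, 0, 10, 10), "non-negative")
})

test_that("FDR adjustment is order-preserving, monotone and matches step-up", {
  expect_equal(fdr_adjust(0.04), 0.04)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(3)
  p <- runif(50)
  bh <- fdr_adjust(p); by <- fdr_adjust(p, "BY")
  expect_true(all(bh >= p - 1e-12))
  expect_true(all(by >= bh - 1e-12))      # harmonic factor >= 1
  expect_true(all(diff(bh[order(p)]) >= -1e-12))  # monotone in p
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("floored log2 ratio reproduces the published TPM arithmetic", {
  expect_equal(log2_ratio(1.21, 6.83), 2.497, tolerance = 1e-3)
  expect_equal(log2_ratio(0, 1.42), log2(142))
  expect_equal(log2_ratio(5, 5), 0)
  expect_equal(log2_ratio(2, 8), 2)
  expect_error(log2_ratio(1, 2, floor = 0), "floor")

  # every retained published TPM pair rounds to its printed log2 value at
  # the printed precision (1 decimal, or integer where printed as such)
  tab <- published_summary("deg_tpm")
  got <- log2_ratio(tab$tpm1, tab$tpm2)
  printed <- tab$printed_log2
  decimals <- ifelse(printed == round(printed), 0, 1)
  expect_true(all(abs(got - printed) <= 0.5 * 10^-decimals + 1e-9))
})

test_that("DEG calling applies FDR and fold thresholds jointly", {
  mk <- function(cond, counts, total) {
    structure(list(genes = data.frame(
      gene_id = names(counts), count = as.integer(counts),
      antisense_count = 0L, tpm = NA_real_),
      condition = cond, clean_total = total), class = "gene_expression")
  }
  e1 <- mk("CON", c(gA = 100L, gB = 100L, gC = 0L, gD = 30L), 1e5)
  e2 <- mk("CS", c(gA = 400L, gB = 130L, gC = 50L, gD = 0L), 1e5)
  d <- call_degs(e1, e2)
  r <- setNames(d$records$call, d$records$gene_id)
  expect_equal(r[["gA"]], "up")     # 4-fold, tiny p
  expect_equal(r[["gB"]], "ns")     # significant-ish but < 2-fold
  expect_equal(r[["gC"]], "up")     # 0 -> 50
  expect_equal(r[["gD"]], "down")
  expect_true(all(d$records$fdr >= d$records$p_value - 1e-12))
  expect_true(all(d$records$x + d$records$y > 0))
  rec <- d$records[d$records$gene_id == "gA", ]
  expect_equal(rec$log2_ratio, 2)
  expect_error(call_degs(e1, e1), "differ")

  # alpha monotonicity: stricter threshold yields a subset of calls
  d_strict <- call_degs(e1, e2, alpha = 1e-6)
  called <- function(x) x$records$gene_id[x$records$call != "ns"]
  expect_true(all(called(d_strict) %in% called(d)))
})

test_that("predominantly up-shifted simulations yield more up than down calls", {
  ref <- simulate_transcriptome(300, c(100, 300), seed = 61)
  tr <- assign_ground_truth(ref, de_fraction = 0.2, fold_values = 8,
                            conditions = c("CON", "CS"), prob_up = 0.9,
                            seed = 62)
  idx <- build_index(ref)
  exprs <- lapply(c("CON", "CS"), function(cond) {
    rr <- simulate_tag_reads(ref, tr, cond, 3e4,
                             seed = 63 + match(cond, c("CON", "CS")))
    lib <- extract_clean_tags(rr)
    tpm_normalize(gene_counts(map_tags(lib, idx), lib))
  })
  s <- summary(call_degs(exprs[[1]], exprs[[2]]))
  expect_gt(s$up, s$down)
})

test_that("hypergeometric enrichment matches combinatorial oracles", {
  bg <- paste0("g", 1:10)
  tm <- data.frame(gene_id = bg[1:5], term_id = "T1")
  out <- enrich_terms(bg[1:5], bg, tm)
  expect_equal(out$p_value, 1 / choose(10, 5))   # all 5 draws in the term
  expect_equal(out$k, 5)

  # overlap at its expectation is unremarkable
  bg2 <- paste0("g", 1:100)
  tm2 <- data.frame(gene_id = bg2[1:40], term_id = "T2")
  set.seed(4)
  degs <- c(bg2[1:8], bg2[41:52])   # k = 8 = n*K/N = 20*40/100
  out2 <- enrich_terms(degs, bg2, tm2)
  expect_gt(out2$p_value, 0.3)

  # empty terms are skipped, not an error
  tm3 <- data.frame(gene_id = "not_in_background", term_id = "T3")
  expect_equal(nrow(enrich_terms(bg[1:2], bg, tm3)), 0)
  expect_error(enrich_terms(bg[1:2], character(0), tm), "background")
  expect_error(enrich_terms("zz", bg, tm), "subset")
})
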