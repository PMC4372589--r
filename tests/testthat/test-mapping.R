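test_that("virtual tag index equals brute-force enumeration of CATG 21-mers", {
  ref <- toy_transcriptome()
  idx <- build_index(ref)
  expect_equal(idx$entries$tag[idx$entries$gene_id == "g1"],
               "CATGACGTACGTACGTACGTA")
  expect_equal(idx$n_genes_with_catg, 2)   # g3 has no site on either strand

  for (seed in c(2, 9)) {
    ref <- simulate_transcriptome(10, c(60, 200), seed = seed)
    got <- build_index(ref)$entries
    want <- brute_index_tags(ref)
    key <- function(d) sort(paste(d$tag, d$gene_id, d$pos, d$strand))
    expect_identical(key(got), key(want))
  }
})

test_that("mapping statuses match the brute-force Hamming oracle", {
  set.seed(42)
  ref <- simulate_transcriptome(12, c(60, 150), seed = 33)
  idx <- build_index(ref)
  # query mix: exact reference tags, 1-bp corruptions, random junk
  pool <- unique(idx$entries$tag)
  corrupt <- vapply(sample(pool, 30, replace = TRUE), function(t) {
    p <- sample(5:21, 1)
    b <- setdiff(c("A", "C", "G", "T"), substr(t, p, p))
    substr(t, p, p) <- sample(b, 1)
    t
  }, "")
  queries <- unique(c(sample(pool, 20), corrupt, rand_tag(30)))
  lib <- lib_from_counts(setNames(rep(2L, length(queries)), queries))

  got <- map_tags(lib, idx)$assignments
  want <- brute_map(names(lib$counts), idx$entries)
  got <- got[order(got$tag), ]; want <- want[order(want$tag), ]
  expect_equal(got$status, want$status)
  expect_equal(got$gene_id, want$gene_id)
  expect_equal(got$strand, want$strand)
  expect_equal(got$mismatch, want$mismatch)

  # tightening 1 -> 0 mismatches never increases the mapped count
  got0 <- map_tags(lib, idx, max_mismatch = 0)$assignments
  expect_lte(sum(got0$status != "unknown"), sum(got$status != "unknown"))
  # and exact hits are untouched by the mismatch budget
  expect_identical(got0$gene_id[got0$mismatch %in% 0],
                   got$gene_id[got$mismatch %in% 0])
})

test_that("ambiguity is defined at gene level with sense-first resolution", {
  shared <- paste0("CATG", strrep("A", 17))
  uniq <- paste0("CATG", strrep("C", 17))
  near2 <- paste0("CATG", "G", strrep("A", 16))  # dist 1 from `shared`
  ref <- structure(data.frame(
    gene_id = c("gA", "gB"),
    sequence = c(paste0(shared, strrep("T", 5), uniq),
                 paste0(near2, strrep("T", 20)))),
    class = c("reference_transcriptome", "data.frame"))
  idx <- build_index(ref)

  lib <- lib_from_counts(setNames(c(3L, 4L, 2L),
                                  c(shared, uniq, paste0("CATG", "T", strrep("A", 16)))))
  m <- map_tags(lib, idx)$assignments
  m <- m[order(m$tag), ]
  # `shared` hits gA exactly; the exact hit shields it from gB's 1-mismatch
  expect_equal(m$status[m$tag == shared], "unambiguous")
  expect_equal(m$gene_id[m$tag == shared], "gA")
  # third tag is at distance 1 from both gA's and gB's tags -> ambiguous
  expect_equal(m$status[m$tag == paste0("CATG", "T", strrep("A", 16))],
               "ambiguous")

  # multi-position hits within one gene stay unambiguous
  twice <- structure(data.frame(
    gene_id = "gC",
    sequence = paste0(uniq, strrep("T", 4), uniq)),
    class = c("reference_transcriptome", "data.frame"))
  m2 <- map_tags(lib_from_counts(setNames(2L, uniq)),
                 build_index(twice))$assignments
  expect_equal(m2$status, "unambiguous")
  expect_equal(m2$gene_id, "gC")
})

test_that("anchor policy is inert for CATG-anchored tags and references", {
  # clean tags and virtual tags both carry the CATG anchor, so allowing a
  # mismatch inside the anchor can never create a new hit; the two
  # policies must agree on any valid library
  ref <- simulate_transcriptome(8, c(60, 120), seed = 4)
  idx <- build_index(ref)
  qs <- unique(c(sample(unique(idx$entries$tag), 5), rand_tag(20)))
  lib <- lib_from_counts(setNames(rep(2L, length(qs)), qs))
  expect_identical(map_tags(lib, idx, anchor_exact = TRUE)$assignments,
                   map_tags(lib, idx, anchor_exact = FALSE)$assignments)
})

test_that("gene counts conserve copies across mapping statuses", {
  ref <- simulate_transcriptome(30, c(80, 200), seed = 12)
  tr <- assign_ground_truth(ref, de_fraction = 0, fold_values = 2, seed = 1)
  rr <- simulate_tag_reads(ref, tr, "CON", 5000, error_rate = 0.01,
                           empty_read_rate = 0.05, seed = 6)
  lib <- extract_clean_tags(rr)
  m <- map_tags(lib, build_index(ref))
  expr <- gene_counts(m, lib)
  a <- m$assignments
  un <- a$status == "unambiguous"
  total <- sum(expr$genes$count) + sum(expr$genes$antisense_count) +
    sum(a$count[a$status == "ambiguous"]) +
    sum(a$count[a$status == "unknown"])
  expect_equal(total, lib$clean_total)
  # ambiguous copies appear in no gene's count
  expect_equal(sum(expr$genes$count) + sum(expr$genes$antisense_count),
               sum(a$count[un]))
})

test_that("error-free per-gene counts equal the simulator's emitted reads", {
  ref <- simulate_transcriptome(25, c(80, 200), catg_fraction = 1, seed = 14)
  tr <- assign_ground_truth(ref, de_fraction = 0, fold_values = 2, seed = 1)
  rr <- simulate_tag_reads(ref, tr, "CON", 4000, error_rate = 0,
                           empty_read_rate = 0, seed = 7)
  lib <- extract_clean_tags(rr, min_copy = 1)
  expr <- gene_counts(map_tags(lib, build_index(ref)), lib)
  emitted <- rr$gene_reads[rr$gene_reads > 0]
  got <- setNames(expr$genes$count, expr$genes$gene_id)
  expect_identical(got[names(emitted)], emitted)
})

test_that("TPM normalization divides by the clean total", {
  expr <- structure(list(
    genes = data.frame(gene_id = c("a", "b"), count = c(1L, 0L),
                       antisense_count = 0L, tpm = NA_real_),
    condition = "X", clean_total = 1e6), class = "gene_expression")
  out <- tpm_normalize(expr)
  expect_equal(out$genes$tpm, c(1, 0))
  expr$clean_total <- 0
  expect_error(tpm_normalize(expr), "clean_total")

  # sum(TPM) identity against mapped fraction
  ref <- simulate_transcriptome(20, c(80, 150), seed = 3)
  tr <- assign_ground_truth(ref, de_fraction = 0, fold_values = 2, seed = 1)
  rr <- simulate_tag_reads(ref, tr, "CON", 3000, seed = 2)
  lib <- extract_clean_tags(rr)
  e <- tpm_normalize(gene_counts(map_tags(lib, build_index(ref)), lib))
  expect_equal(sum(e$genes$tpm),
               sum(e$genes$count) / lib$clean_total * 1e6)
  expect_lte(sum(e$genes$tpm), 1e6)
})

test_that("published mapping split percentages are reproduced", {
  mc <- published_summary("mapping_counts")
  cnt <- setNames(mc$count, mc$metric)
  expect_equal(deepsage:::pct(cnt[["unambiguous"]],
                              cnt[["reference_tags_mapped"]]), 96.31)
  expect_equal(deepsage:::pct(cnt[["ambiguous"]],
                              cnt[["reference_tags_mapped"]]), 3.69)
  expect_equal(cnt[["unambiguous"]] + cnt[["ambiguous"]],
               cnt[["reference_tags_mapped"]])
})
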