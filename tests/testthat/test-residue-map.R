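fake_scores <- function(guide_id, z, editor = "CBE", cell_line = "cl") {
  tibble::tibble(cell_line = cell_line, editor = editor, guide_id = guide_id,
                 mean_rpm_t0 = 1000, mean_rpm_end = 1000, mean_raw_t0 = 1000,
                 pass_filter = TRUE, l2fc = z, z = z)
}

test_that("residues aggregate the minimum contributing z", {
  preds <- dplyr::bind_rows(
    prediction_row("g1", "CBE", "missense", residues = c(10L, 11L)),
    prediction_row("g2", "CBE", "missense", residues = 10L),
    prediction_row("g3", "CBE", "synonymous", residues = 5L,
                   alt_aa = "A", ref_aa = "A")
  )
  sc <- fake_scores(c("g1", "g2", "g3"), c(-3, -0.5, -4))
  map <- build_residue_map(sc, preds, protein_length = 20)
  expect_equal(map$aggregate_z[map$residue == 10], -3)
  expect_equal(map$n_guides[map$residue == 10], 2L)
  expect_equal(map$aggregate_z[map$residue == 11], -3)
  expect_equal(map$n_guides[map$residue == 11], 1L)
  # synonymous guides contribute nowhere, even with extreme z
  expect_equal(map$n_guides[map$residue == 5], 0L)
  expect_true(is.na(map$hit[map$residue == 5]))
  # hit calls at the default threshold
  expect_true(all(map$hit[map$residue %in% c(10, 11)]))

  mean_map <- build_residue_map(sc, preds, 20, aggregate = "mean")
  expect_equal(mean_map$aggregate_z[mean_map$residue == 10], -1.75)
})

test_that("hits respect the threshold and uncovered residues stay NA", {
  preds <- dplyr::bind_rows(
    prediction_row("g1", "CBE", "missense", residues = 1L),
    prediction_row("g2", "CBE", "missense", residues = 2L)
  )
  sc <- fake_scores(c("g1", "g2"), c(-2, -1.5))
  map <- build_residue_map(sc, preds, 3, hit_z = -2)
  expect_true(map$hit[1])    # z = -2 is at the threshold
  expect_false(map$hit[2])   # -1.5 is not a hit
  expect_true(is.na(map$hit[3]))
})

test_that("splice guides contribute to the flanking exonic residue", {
  preds <- prediction_row("g1", "CBE", "splice_donor", splice_residue = 7L)
  sc <- fake_scores("g1", -2.6)
  map <- build_residue_map(sc, preds, 10)
  expect_equal(map$aggregate_z[map$residue == 7], -2.6)
  expect_equal(sum(map$n_guides), 1L)
})

test_that("stop-codon changes fold onto the last residue; beyond is an error", {
  preds <- prediction_row("g1", "CBE", "stop_loss", residues = 11L,
                          ref_aa = "*", alt_aa = "Q")
  sc <- fake_scores("g1", -2.2)
  map <- build_residue_map(sc, preds, 10)
  expect_equal(map$aggregate_z[map$residue == 10], -2.2)
  preds_bad <- prediction_row("g1", "CBE", "missense", residues = 12L)
  expect_error(build_residue_map(sc, preds_bad, 10), "beyond")
})

test_that("filtered guides never contribute to the map", {
  sc <- fake_scores(c("g1", "g2"), c(-3, -3))
  sc$pass_filter[2] <- FALSE
  sc$z[2] <- NA
  preds <- dplyr::bind_rows(
    prediction_row("g1", "CBE", "missense", residues = 1L),
    prediction_row("g2", "CBE", "missense", residues = 2L)
  )
  map <- build_residue_map(sc, preds, 2)
  expect_equal(map$n_guides, c(1L, 0L))
})

test_that("adding a weaker guide never changes a min-aggregated residue", {
  set.seed(21)
  base_preds <- dplyr::bind_rows(lapply(1:30, function(i) {
    prediction_row(sprintf("g%02d", i), "CBE", "missense",
                   residues = sample(1:15, sample(1:2, 1)))
  }))
  sc <- fake_scores(sprintf("g%02d", 1:30), rnorm(30))
  map1 <- build_residue_map(sc, base_preds, 15)
  extra <- prediction_row("gx", "CBE", "missense", residues = 1:15)
  sc2 <- dplyr::bind_rows(sc, fake_scores("gx", max(sc$z) + 1))
  map2 <- build_residue_map(sc2, dplyr::bind_rows(base_preds, extra), 15)
  expect_equal(map2$aggregate_z, map1$aggregate_z)
})

test_that("the worked 4-residue enrichment example gives p = 1/6", {
  map <- tibble::tibble(residue = 1:4, n_guides = 1L,
                        aggregate_z = c(-3, -2.5, 0, 0),
                        hit = c(TRUE, TRUE, FALSE, FALSE))
  track <- tibble::tibble(label = "dom", start = 1, end = 2)
  enr <- domain_enrichment(map, track)
  expect_equal(enr$p_value, 1 / 6, tolerance = 1e-12)
  expect_equal(enr$hits_in, 2)
  expect_equal(enr$covered_in, 2)
})

test_that("a domain with zero hits has one-sided p = 1", {
  map <- tibble::tibble(residue = 1:6, n_guides = 1L,
                        aggregate_z = c(0, 0, -3, -3, 0, 0),
                        hit = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  enr <- domain_enrichment(map, tibble::tibble(label = "d", start = 1, end = 2))
  expect_equal(enr$p_value, 1)
})

test_that("hypergeometric p matches exhaustive enumeration on small universes", {
  set.seed(22)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    H <- sample(0:n, 1)
    k <- sample(1:(n - 1), 1)
    hit <- rep(FALSE, n); hit[sample.int(n, H)] <- TRUE
    map <- tibble::tibble(residue = 1:n, n_guides = 1L,
                          aggregate_z = ifelse(hit, -3, 0), hit = hit)
    enr <- domain_enrichment(map, tibble::tibble(label = "d", start = 1, end = k))
    expect_equal(enr$p_value, enum_hyper_p(n, H, k, sum(hit[1:k])),
                 tolerance = 1e-12)
  }
})

test_that("enrichment p is invariant under relabeling outside the domain", {
  map <- tibble::tibble(residue = 1:10, n_guides = 1L,
                        aggregate_z = c(-3, -3, 0, 0, -3, 0, 0, -3, 0, 0),
                        hit = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE,
                                TRUE, FALSE, FALSE))
  p1 <- domain_enrichment(map, tibble::tibble(label = "d", start = 1, end = 3))$p_value
  # permute the hit pattern outside residues 1..3 (same outside totals)
  map2 <- map
  map2$hit[4:10] <- c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  map2$aggregate_z[4:10] <- ifelse(map2$hit[4:10], -3, 0)
  p2 <- domain_enrichment(map2, tibble::tibble(label = "d", start = 1, end = 3))$p_value
  expect_equal(p1, p2)
})

test_that("pathogenicity classes are tested as labels", {
  map <- tibble::tibble(residue = 1:8, n_guides = 1L,
                        aggregate_z = c(-3, -3, -3, 0, 0, 0, 0, 0),
                        hit = c(TRUE, TRUE, TRUE, rep(FALSE, 5)))
  track <- tibble::tibble(residue = 1:8,
                          class = rep(c("pathogenic", "benign"), each = 4))
  enr <- domain_enrichment(map, track)
  expect_setequal(enr$label, c("pathogenic", "benign"))
  expect_true(enr$p_value[enr$label == "pathogenic"] <
                enr$p_value[enr$label == "benign"])
})

test_that("concordance is the Pearson correlation over shared passing guides", {
  a <- fake_scores(c("g1", "g2", "g3"), c(-1, 0, 1))
  b <- fake_scores(c("g1", "g2", "g3"), c(-1, 0, 1), cell_line = "cl2")
  cc <- screen_concordance(a, b)
  expect_equal(cc$r2, 1)
  expect_equal(cc$n_shared, 3L)

  b2 <- fake_scores(c("g1", "g2", "g3"), c(1, 0, -1))
  cc2 <- screen_concordance(a, b2)
  expect_equal(cc2$r, -1)
  expect_equal(cc2$r2, 1)

  # a guide failing filters in one screen is dropped from the intersection
  a3 <- fake_scores(c("g1", "g2", "g3", "g4"), c(-1, 0, 1, 2))
  b3 <- fake_scores(c("g1", "g2", "g3", "g4"), c(-1, 0, 1, 2), cell_line = "x")
  b3$pass_filter[4] <- FALSE
  expect_equal(screen_concordance(a3, b3)$n_shared, 3L)

  expect_error(screen_concordance(a[1:2, ], b), ">= 3")
})
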