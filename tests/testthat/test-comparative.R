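test_that("overlap counts, sharing fractions and margins reconcile", {
  u <- sprintf("P%03d", 1:100)
  a <- u[1:10]; b <- c(u[3:10], u[20:25])
  ov <- overlap_counts(a, b, u)
  expect_equal(ov$a, 8)
  expect_equal(ov$b, 2)
  expect_equal(ov$c, 6)
  expect_equal(ov$d, 84)
  expect_equal(ov$sharing_a, 0.8)
  expect_equal(ov$n_a, ov$a + ov$b)              # |A| = |A∩B| + |A\B|
  expect_equal(ov$a + ov$b + ov$c + ov$d, length(u))

  same <- overlap_counts(a, a, u)
  expect_equal(c(same$sharing_a, same$sharing_b), c(1, 1))
  disj <- overlap_counts(u[1:5], u[6:10], u)
  expect_equal(c(disj$sharing_a, disj$sharing_b), c(0, 0))
  none <- suppressWarnings(overlap_counts(character(0), a, u))
  expect_true(is.na(none$sharing_a))
  expect_error(overlap_counts(c(a, "Q999"), b, u), "outside universe")
})

test_that("fisher_exact reproduces enumerated two-sided p-values", {
  expect_equal(fisher_exact(rbind(c(3, 1), c(1, 3))), 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact(rbind(c(0, 5), c(5, 0))), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact(rbind(c(2, 2), c(2, 2))), 1.0)
  expect_warning(p0 <- fisher_exact(rbind(c(0, 0), c(3, 4))), "zero margin")
  expect_equal(p0, 1.0)
  expect_error(fisher_exact(rbind(c(0, 0), c(0, 0))), "total")

  withr::local_seed(303)
  for (i in 1:200) {
    tab <- matrix(stats::rpois(4, 5), 2)
    if (sum(tab) == 0) next
    p <- suppressWarnings(fisher_exact(tab))
    expect_equal(p, enum_fisher_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-12, info = paste(tab, collapse = ","))
    # cross-check against the reference implementation where well-defined
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-8)
    }
  }
})

test_that("X-linked fold enrichment is the ratio of on-X to off-X frequency", {
  prom <- promoter_set(tibble::tibble(
    promoter_id = sprintf("P%04d", 1:1100),
    gene_id = sprintf("G%04d", 1:1100),
    chrom = c(rep("chrX", 100), rep("chr1", 1000)),
    strand = "+", tss = seq(10000, by = 10000, length.out = 1100)))
  ids <- prom$promoter_id
  target <- c(ids[1:30], ids[101:200])             # 30% on X vs 10% off X
  expect_equal(x_linked_fold(target, prom), 3.0)
  expect_equal(x_linked_fold(c(ids[1:10], ids[101:200]), prom), 1.0)
  expect_equal(x_linked_fold(ids[101:200], prom), 0.0)
  expect_error(x_linked_fold(ids[1:30], prom), "off-X")
  no_x <- promoter_set(tibble::tibble(
    promoter_id = "P1", gene_id = "G1", chrom = "chr1", strand = "+", tss = 100L))
  expect_error(x_linked_fold("P1", no_x), "X chromosome")
})

test_that("present calls use the >= half-of-cells rule, boundary inclusive", {
  expect_true(present_call(c(rep(1, 10), rep(0, 10))))
  expect_false(present_call(c(rep(1, 9), rep(0, 11))))
  expect_true(present_call(rep(1, 20)))
  expect_error(present_call(rep(1, 19), n_cells = 20), "19")
  expect_error(present_call(c(1, 2, 0)), "binary")
  # generalized threshold: ceil(n/2)
  expect_true(present_call(c(1, 1, 1, 0, 0)))     # 3 of 5
  expect_false(present_call(c(1, 1, 0, 0, 0)))    # 2 of 5
})

test_that("percent expressed per class is exact arithmetic with NA empty states", {
  rec <- tibble::tibble(promoter_id = sprintf("P%03d", 1:200),
                        state = rep(c("K4", "bivalent"), each = 100))
  pres <- tibble::tibble(promoter_id = rec$promoter_id,
                         present = c(rep(TRUE, 100), rep(TRUE, 51), rep(FALSE, 49)))
  out <- percent_expressed_by_class(rec, pres)
  expect_equal(out$percent_expressed[out$state == "K4"], 100)
  expect_equal(out$percent_expressed[out$state == "bivalent"], 51)
  expect_true(is.na(out$percent_expressed[out$state == "K27"]))
  expect_error(percent_expressed_by_class(rec, pres[1:10, ]), "universe")
})

test_that("three-way Venn counts partition the union and bound intersections", {
  ab <- three_way_overlap(c("a", "b"), c("a", "b"), c("a", "b"))
  expect_equal(ab$count[ab$region == "ABC"], 2)
  expect_equal(sum(ab$count), 2)

  dj <- three_way_overlap("x", "y", "z")
  expect_equal(dj$count[dj$region %in% c("A_only", "B_only", "C_only")], c(1, 1, 1))
  expect_equal(sum(dj$count), 3)

  withr::local_seed(404)
  u <- sprintf("P%03d", 1:60)
  for (i in 1:25) {
    A <- sample(u, 25); B <- sample(u, 25); C <- sample(u, 25)
    v <- three_way_overlap(A, B, C)
    cnt <- stats::setNames(v$count, v$region)
    triple <- cnt[["ABC"]]
    expect_lte(triple, length(intersect(A, B)))
    expect_lte(triple, length(intersect(A, C)))
    expect_lte(triple, length(intersect(B, C)))
    # reconcile with pairwise overlap counts
    ov <- overlap_counts(A, B, u)
    expect_equal(ov$a, cnt[["AB"]] + triple)
    expect_equal(sum(cnt), length(unique(c(A, B, C))))
  }
})
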