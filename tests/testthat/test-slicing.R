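test_that("slices partition the sample into near-equal contiguous stripes", {
  set.seed(7)
  profiles <- data.frame(person_id = sprintf("p%03d", 1:100),
                         wim = rnorm(100), wisd = abs(rnorm(100)))
  for (dir in c("antidiagonal", "diagonal", "horizontal")) {
    for (k in c(1, 3, 7, 10)) {
      cells <- slice_cells(profiles, dir, k)
      expect_length(cells, k)
      ids <- unlist(lapply(cells, `[[`, "person_ids"))
      expect_setequal(ids, profiles$person_id)        # union = sample
      expect_equal(anyDuplicated(ids), 0L)            # disjoint
      sizes <- vapply(cells, `[[`, integer(1), "n")
      expect_lte(max(sizes) - min(sizes), 1L)
      # remainder goes to the earliest stripes
      expect_true(all(diff(sizes) <= 0))
    }
  }
})

test_that("n = 10 into k = 3 gives sizes (4, 3, 3)", {
  profiles <- data.frame(person_id = letters[1:10], wim = 1:10,
                         wisd = c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3))
  sizes <- vapply(slice_cells(profiles, "horizontal", 3), `[[`,
                  integer(1), "n")
  expect_equal(sizes, c(4L, 3L, 3L))
})

test_that("k = 1 returns the full sample identically for every direction", {
  set.seed(2)
  profiles <- data.frame(person_id = sprintf("p%02d", 1:30),
                         wim = rnorm(30), wisd = abs(rnorm(30)))
  cells <- lapply(c("antidiagonal", "diagonal", "horizontal"),
                  function(d) slice_cells(profiles, d, 1)[[1]])
  for (cell in cells) {
    expect_equal(cell$n, 30L)
    expect_setequal(cell$person_ids, profiles$person_id)
    expect_equal(cell$rho_wim_wisd, cells[[1]]$rho_wim_wisd)
  }
})

test_that("stripe order follows the slicing score", {
  set.seed(3)
  profiles <- data.frame(person_id = sprintf("p%03d", 1:200),
                         wim = rnorm(200), wisd = abs(rnorm(200)))
  zw <- as.vector(scale(profiles$wim)); zs <- as.vector(scale(profiles$wisd))
  score <- list(antidiagonal = zw - zs, diagonal = zw + zs,
                horizontal = zs)
  for (dir in names(score)) {
    cells <- slice_cells(profiles, dir, 5)
    maxima <- vapply(cells, function(cell) {
      max(score[[dir]][match(cell$person_ids, profiles$person_id)])
    }, numeric(1))
    expect_true(all(diff(maxima) > 0))   # boundaries never interleave
  }
})

test_that("slicing direction controls the within-stripe WIM-WISD correlation", {
  # independent bivariate normal profile cloud: the Monte-Carlo oracle for
  # the three stripe geometries
  set.seed(42)
  profiles <- data.frame(person_id = sprintf("p%04d", 1:2000),
                         wim = rnorm(2000), wisd = rnorm(2000))
  anti <- vapply(slice_cells(profiles, "antidiagonal", 8), `[[`,
                 numeric(1), "rho_wim_wisd")
  diag_ <- vapply(slice_cells(profiles, "diagonal", 8), `[[`,
                  numeric(1), "rho_wim_wisd")
  horiz <- vapply(slice_cells(profiles, "horizontal", 8), `[[`,
                  numeric(1), "rho_wim_wisd")
  expect_true(all(anti > 0))
  expect_true(all(diag_ < 0))
  expect_lt(abs(mean(horiz)), 0.1)
})

test_that("degenerate and invalid slicing requests fail loudly", {
  profiles <- data.frame(person_id = letters[1:5], wim = rep(1, 5),
                         wisd = rep(2, 5))
  expect_error(slice_cells(profiles, "diagonal", 6), "exceeds sample size")
  expect_error(slice_cells(profiles, "diagonal", 0), "k must be")
  expect_error(slice_cells(profiles, "diagonal", 2), "distinct slicing scores")
})

test_that("spearman_rho matches the brute-force rank formula and cor.test", {
  x <- c(1, 2, 3, 4, 6, 5, 8, 7)
  y <- c(2, 1, 4, 3, 5, 7, 6, 8)
  rx <- rank(x); ry <- rank(y)
  brute <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  rs <- spearman_rho(x, y)
  expect_equal(rs$rho, brute, tolerance = 1e-12)
  expect_equal(rs$rho, unname(cor.test(x, y, method = "spearman")$estimate),
               tolerance = 1e-12)
  # ties handled by mid-ranks
  xt <- c(1, 1, 2, 3, 4, 4); yt <- c(2, 3, 3, 5, 7, 7)
  expect_equal(spearman_rho(xt, yt)$rho,
               cor(rank(xt), rank(yt)), tolerance = 1e-12)
  # perfect monotone association
  expect_equal(spearman_rho(1:6, (1:6)^3)$rho, 1)
  expect_true(is.na(spearman_rho(rep(1, 6), 1:6)$rho))
})

test_that("enumerate_sweep emits the triangular cell count", {
  expect_equal(nrow(enumerate_sweep(1)), 3L)
  e7 <- enumerate_sweep(7)
  expect_equal(nrow(e7), 84L)
  # exhaustive count formula check
  for (km in c(2, 5, 13, 30, 50))
    expect_equal(nrow(enumerate_sweep(km)), 3 * km * (km + 1) / 2)
  expect_equal(nrow(enumerate_sweep(20, "horizontal")), 210L)
  # every (direction, k) block holds exactly k cells indexed 1..k
  blk <- subset(e7, direction == "diagonal" & k == 5)
  expect_equal(sort(blk$slice_index), 1:5)
})
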