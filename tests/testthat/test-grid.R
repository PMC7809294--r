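test_that("grid construction counts nodes and rejects bad spacings", {
  g <- build_grid(c(1, 1, 1) * 1e-3, 0.5e-3)
  expect_identical(g$n, c(3L, 3L, 3L))
  expect_equal(prod(g$n), 27)

  g2 <- build_grid(c(10, 10, 5) * 1e-3, 0.25e-3)
  expect_identical(g2$n, c(41L, 41L, 21L))

  expect_error(build_grid(c(1, 1, 1) * 1e-3, 0.3e-3), "does not divide")
  expect_error(build_grid(c(1, 1, 1) * 1e-3, 0.3e-3), "axis x, y, z")
  expect_error(build_grid(c(1, 1, 1) * 1e-3, -1e-4), "positive")
  expect_equal(g2$extent, (g2$n - 1L) * g2$h)
})

test_that("rasterization equals the brute-force point-membership oracle", {
  g <- build_grid(c(4e-3, 4e-3, 4e-3), 0.5e-3)
  els <- list(
    electrode("plate", center = c(1e-3, 1e-3, 1e-3), polarity = "anode",
              size = c(1e-3, 1e-3, 1e-3)),
    electrode("needle", center = c(3e-3, 3e-3, 2e-3), polarity = "cathode",
              radius = 0.6e-3, length = 2.4e-3, axis = c(0, 1, 1)))
  lab <- rasterize_electrodes(g, els)
  expect_identical(lab$label, brute_force_labels(g, els))
  expect_gt(sum(lab$label == 1L), 0)
  expect_gt(sum(lab$label == 2L), 0)
})

test_that("axis-aligned unit plate on a half-spacing grid claims all 27 nodes", {
  g <- build_grid(c(1, 1, 1) * 1e-3, 0.5e-3)
  els <- list(
    electrode("plate", center = c(0.5e-3, 0.5e-3, 0.5e-3), polarity = "anode",
              size = c(1e-3, 1e-3, 1e-3)))
  # membership check against the brute-force oracle needs no cathode
  expect_identical(brute_force_labels(g, els), array(1L, g$n))
})

test_that("empty electrode list labels every node tissue", {
  g <- build_grid(c(2e-3, 2e-3, 2e-3), 0.5e-3)
  lab <- rasterize_electrodes(g, list())
  expect_true(all(lab$label == 0L))
})

test_that("a thin needle centered on a node column claims exactly that column", {
  g <- build_grid(c(2e-3, 2e-3, 2e-3), 0.5e-3)
  els <- list(
    electrode("needle", center = c(1e-3, 1e-3, 1e-3), polarity = "anode",
              radius = 0.4 * g$h, length = 2e-3),
    electrode("needle", center = c(0, 0, 1e-3), polarity = "cathode",
              radius = 0.4 * g$h, length = 2e-3))
  lab <- rasterize_electrodes(g, els)
  anode_nodes <- which(lab$label == 1L, arr.ind = TRUE)
  expect_true(all(anode_nodes[, 1] == 3L & anode_nodes[, 2] == 3L))
  expect_identical(sort(anode_nodes[, 3]), seq_len(g$n[3]))
})

test_that("swapping polarities only permutes the two electrode label classes", {
  fx <- needle_fixture()
  swapped <- lapply(fx$electrodes, function(e) {
    e$polarity <- if (e$polarity == "anode") "cathode" else "anode"
    e
  })
  lab2 <- rasterize_electrodes(fx$grid, swapped)
  expect_identical(lab2$label == 0L, fx$labels$label == 0L)
  expect_identical(lab2$label == 1L, fx$labels$label == 2L)
  expect_identical(lab2$label == 2L, fx$labels$label == 1L)
})

test_that("overlapping electrodes and out-of-domain electrodes are rejected", {
  g <- build_grid(c(4e-3, 4e-3, 4e-3), 0.5e-3)
  overlap <- list(
    electrode("plate", center = c(2e-3, 2e-3, 2e-3), polarity = "anode",
              size = c(2e-3, 2e-3, 2e-3)),
    electrode("plate", center = c(2.5e-3, 2e-3, 2e-3), polarity = "cathode",
              size = c(2e-3, 2e-3, 2e-3)))
  expect_error(rasterize_electrodes(g, overlap), "overlap")
  outside <- list(
    electrode("plate", center = c(20e-3, 20e-3, 20e-3), polarity = "anode",
              size = c(1e-3, 1e-3, 1e-3)),
    electrode("plate", center = c(2e-3, 2e-3, 2e-3), polarity = "cathode",
              size = c(1e-3, 1e-3, 1e-3)))
  expect_error(rasterize_electrodes(g, outside), "no grid node")
})

test_that("grid refinement changes electrode volume by at most a surface layer", {
  el <- list(
    electrode("needle", center = c(4e-3, 4e-3, 4e-3), polarity = "anode",
              radius = 1.2e-3, length = 4e-3),
    electrode("plate", center = c(1e-3, 1e-3, 1e-3), polarity = "cathode",
              size = c(1.5e-3, 1.5e-3, 1.5e-3)))
  vol <- function(h) {
    g <- build_grid(c(8e-3, 8e-3, 8e-3), h)
    lab <- rasterize_electrodes(g, el)
    sum(lab$label == 1L) * g$h^3
  }
  v1 <- vol(0.5e-3); v2 <- vol(0.25e-3)
  # cylinder surface area ~ 2*pi*r*L + 2*pi*r^2
  surf <- 2 * pi * 1.2e-3 * 4e-3 + 2 * pi * (1.2e-3)^2
  expect_lt(abs(v1 - v2), surf * 0.5e-3)
})

test_that("boundary faces classify into tissue-air and electrode-air by exposure", {
  # interior electrodes: every boundary face is tissue-air
  fx <- needle_fixture()
  lab <- fx$labels
  expect_equal(lab$faces$n_electrode_air, 0)
  expect_equal(lab$faces$n_tissue_air,
               2 * prod(fx$grid$n[c(1, 2)]) + 2 * prod(fx$grid$n[c(1, 3)]) +
                 2 * prod(fx$grid$n[c(2, 3)]))

  # plate flush with the top face, fully exposed: top faces over the plate
  # are electrode-air, and exposure 0 removes them all
  g <- build_grid(c(4e-3, 4e-3, 2e-3), 0.5e-3)
  mk <- function(expo) list(
    electrode("plate", center = c(1e-3, 2e-3, 2e-3), polarity = "anode",
              size = c(1e-3, 1e-3, 0.5e-3), exposed_fraction = expo),
    electrode("plate", center = c(3e-3, 2e-3, 2e-3), polarity = "cathode",
              size = c(1e-3, 1e-3, 0.5e-3), exposed_fraction = expo))
  lab1 <- classify_boundaries(g, rasterize_electrodes(g, mk(1)))
  top <- lab1$faces$tag$z1
  plate_top <- lab1$label[, , g$n[3]] > 0L
  expect_true(all(top[plate_top] == "electrode-air"))
  expect_true(all(top[!plate_top] == "tissue-air"))
  expect_equal(lab1$faces$n_electrode_air, sum(plate_top))

  lab0 <- classify_boundaries(g, rasterize_electrodes(g, mk(0)))
  expect_equal(lab0$faces$n_electrode_air, 0)
})
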