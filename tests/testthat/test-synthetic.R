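# Synthetic-data generator: spacing and determinism invariants, ground-truth
# calibration of responder fractions, micropattern packing, LFQ structure.

min_pairwise <- function(cells) {
  d <- dist(cbind(cells$x_um, cells$y_um))
  if (length(d)) min(d) else Inf
}

test_that("empty configuration yields a valid empty field", {
  cfg <- generator_config(n_colonies = 0, n_singles = 0, seed = 1)
  f <- generate_colony_field(cfg)
  expect_s3_class(f, "popc_field")
  expect_identical(nrow(f$cells), 0L)
})

test_that("singles are mutually separated by twice the spacing and flagged", {
  cfg <- generator_config(n_colonies = 0, n_singles = 50,
                          cell_spacing_um = 15, seed = 11)
  f <- generate_colony_field(cfg)
  expect_identical(nrow(f$cells), 50L)
  expect_true(all(f$cells$true_is_single))
  expect_gte(min_pairwise(f$cells), 30)
})

test_that("colony cells are compact: every non-single has a close neighbor", {
  cfg <- generator_config(n_colonies = 5, colony_cells_dist = c(20, 40),
                          n_singles = 0, cell_spacing_um = 15,
                          field_width_um = 2500, field_height_um = 2500,
                          seed = 12)
  f <- generate_colony_field(cfg)
  xy <- cbind(f$cells$x_um, f$cells$y_um)
  D <- as.matrix(dist(xy)); diag(D) <- Inf
  expect_true(all(apply(D, 1, min) <= 1.5 * 15))
  expect_gte(min(D), 15)  # exact spacing invariant
})

test_that("same config and seed regenerate byte-identical fields", {
  cfg <- generator_config(n_colonies = 3, n_singles = 20, seed = 42)
  f1 <- generate_colony_field(cfg)
  f2 <- generate_colony_field(cfg)
  expect_identical(f1$cells, f2$cells)
  lfq1 <- generate_lfq_table(100, noise_sd = 0.3, seed = 9)
  lfq2 <- generate_lfq_table(100, noise_sd = 0.3, seed = 9)
  expect_identical(as.data.frame(lfq1), as.data.frame(lfq2))
})

test_that("micropattern population fills the disk at near-hexagonal packing", {
  cfg <- generator_config(cell_spacing_um = 12, pattern_diameter_um = 200,
                          seed = 3)
  f <- generate_micropattern_population(cfg)
  r <- sqrt((f$cells$x_um - 100)^2 + (f$cells$y_um - 100)^2)
  expect_true(all(r <= 100))
  expect_gte(min_pairwise(f$cells), 12)
  hex_count <- pi * 100^2 / (sqrt(3) / 2 * 12^2)
  expect_gt(nrow(f$cells), 0.8 * hex_count)
  expect_lt(nrow(f$cells), 1.2 * hex_count)
})

test_that("degenerate micropattern smaller than the spacing holds one cell", {
  cfg <- generator_config(cell_spacing_um = 15, pattern_diameter_um = 10,
                          seed = 4)
  f <- generate_micropattern_population(cfg)
  expect_identical(nrow(f$cells), 1L)
  expect_equal(c(f$cells$x_um, f$cells$y_um), c(5, 5))
})

test_that("responder labels follow the configured degree probabilities", {
  cfg <- generator_config(n_colonies = 0, n_singles = 0, seed = 21,
                          response_prob_by_degree = c(`0` = 0.8))
  # large synthetic cohort of degree-0 cells placed on a coarse grid
  g <- expand.grid(x_um = (0:99) * 40, y_um = (0:99) * 40)
  f <- structure(list(cells = data.frame(cell_id = seq_len(nrow(g)), g,
                                         true_colony_id = NA_integer_,
                                         true_is_single = TRUE),
                      config = cfg, mode = "colony"), class = "popc_field")
  f <- assign_response_intensities(f, cfg, rep(0L, nrow(g)))
  frac <- mean(f$cells$true_responder)
  expect_lt(abs(frac - 0.8), 0.01)  # binomial tolerance at n = 10,000

  expect_error(assign_response_intensities(f, cfg, rep(3L, nrow(g))),
               "edge degree")
})

test_that("zero and unit response probabilities are degenerate as expected", {
  g <- expand.grid(x_um = (0:9) * 40, y_um = (0:9) * 40)
  mk_field <- function(cfg)
    structure(list(cells = data.frame(cell_id = seq_len(nrow(g)), g,
                                      true_colony_id = NA_integer_,
                                      true_is_single = TRUE),
                   config = cfg, mode = "colony"), class = "popc_field")
  cfg0 <- generator_config(response_prob_by_degree = c(`0` = 0), seed = 5)
  f0 <- assign_response_intensities(mk_field(cfg0), cfg0, rep(0L, 100))
  expect_false(any(f0$cells$true_responder))
  cfg1 <- generator_config(response_prob_by_degree = c(`0` = 1), seed = 5)
  f1 <- assign_response_intensities(mk_field(cfg1), cfg1, rep(0L, 100))
  expect_true(all(f1$cells$true_responder))
  # mock condition: no responders regardless of probability
  fm <- assign_response_intensities(mk_field(cfg1), cfg1, rep(0L, 100),
                                    condition = "mock")
  expect_false(any(fm$cells$true_responder))
})

test_that("noise-free LFQ tables carry exact ground truth", {
  spec <- c(0.5, 0.25, 0, 1, 0.7)
  lfq <- generate_lfq_table(5, polarity_spec = spec, noise_sd = 0, seed = 2)
  g <- attr(lfq, "groups")
  ap <- as.matrix(as.data.frame(lfq)[, g$apical])
  bl <- as.matrix(as.data.frame(lfq)[, g$basolateral])
  # symmetric proteins: identical side means
  expect_equal(rowMeans(ap)[1], rowMeans(bl)[1])
  # ground-truth apical index equals the spec exactly
  expect_equal(unname(apical_index(lfq)), spec)
  expect_equal(lfq$true_apical_fraction, spec)
  # fully apical/basolateral proteins are undetected on the other side
  expect_true(all(is.na(bl[4, ])))
  expect_true(all(is.na(ap[3, ])))
})

test_that("invalid generator inputs are rejected", {
  expect_error(generator_config(infected_fraction = 1.5), "\\[0, 1\\]")
  expect_error(generator_config(cell_spacing_um = 0), "cell_spacing_um")
  expect_error(generate_lfq_table(10, polarity_spec = 2), "\\[0, 1\\]")
  # infeasible packing: too many singles for the field
  cfg <- generator_config(n_colonies = 0, n_singles = 500,
                          field_width_um = 100, field_height_um = 100,
                          cell_spacing_um = 15, seed = 1)
  expect_error(generate_colony_field(cfg), "infeasible")
})

test_that("rendered images round-trip cell count and centroids", {
  cfg <- generator_config(n_colonies = 0, n_singles = 30,
                          field_width_um = 400, field_height_um = 400,
                          seed = 31)
  f <- generate_colony_field(cfg)
  f <- assign_response_intensities(f, cfg, rep(0L, 30))
  img <- render_field_images(f, pixel_size_um = 1)
  expect_identical(length(setdiff(unique(as.vector(img$labels)), 0L)), 30L)
  seg <- segment_labels(img$intensity, threshold = 0)
  expect_identical(nrow(seg$objects), 30L)
  # centroids recovered within one pixel
  ord <- order(f$cells$x_um)
  sord <- order(seg$objects$x_px)
  expect_true(all(abs(seg$objects$x_px[sord] - f$cells$x_um[ord]) <= 1))
  expect_true(all(abs(seg$objects$y_px[sord] - f$cells$y_um[ord]) <= 1))
  # empty field renders to all-zero images
  e <- render_field_images(generate_colony_field(
    generator_config(n_colonies = 0, n_singles = 0, seed = 1)), 1)
  expect_true(all(e$labels == 0) && all(e$intensity == 0))
})

test_that("overlapping disks at the chosen radius are refused", {
  cfg <- generator_config(n_colonies = 0, n_singles = 5, seed = 6)
  f <- generate_colony_field(cfg)
  expect_error(render_field_images(f, 1, radius_um = 10), "smaller radius")
})
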