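# Spatial annotation: eps estimation, DBSCAN semantics, angular-gap edge
# rule, edge-degree peeling, and equivalence with the brute-force oracle.

lattice <- function(nx, ny, s = 10)
  expand.grid(x_um = (seq_len(nx) - 1) * s, y_um = (seq_len(ny) - 1) * s)

test_that("eps heuristic returns 1.5x the lattice spacing", {
  g <- lattice(10, 10, s = 8)
  eps <- estimate_eps(g, k = 4)
  expect_equal(as.numeric(eps), 1.5 * 8)
  expect_length(attr(eps, "knn_distances"), 100)
})

test_that("eps estimation needs more cells than the neighbor rank", {
  expect_error(estimate_eps(data.frame(x_um = c(0, 1), y_um = c(0, 1)), k = 4),
               "at least k \\+ 1")
})

test_that("eps scales with the coordinates", {
  f <- random_field(60, seed = 3)
  e1 <- as.numeric(estimate_eps(f))
  f2 <- data.frame(x_um = f$x_um * 2, y_um = f$y_um * 2)
  expect_equal(as.numeric(estimate_eps(f2)), 2 * e1)
})

test_that("isolated points are singles; separated grids form two clusters", {
  one <- data.frame(x_um = 5, y_um = 5)
  ann <- annotate_cells(one, annotation_params(eps = 10))
  expect_identical(ann$position_class, "single")
  expect_identical(ann$edge_degree, 0L)
  expect_true(is.na(ann$cluster_id))

  g <- rbind(lattice(5, 5, 10),
             within(lattice(5, 5, 10), x_um <- x_um + 10 * 10 * 1.5 + 200))
  cl <- cluster_cells(g, annotation_params(eps = 15))
  expect_identical(sort(unique(cl$cluster)), c(1L, 2L))
  expect_identical(as.integer(table(cl$cluster)), c(25L, 25L))
})

test_that("5x5 lattice yields one cluster with degrees {16x1, 8x2, 1x3}", {
  g <- lattice(5, 5, 10)
  ann <- annotate_cells(g, annotation_params(eps = 15))
  expect_identical(length(unique(ann$cluster_id)), 1L)
  expect_identical(as.integer(table(ann$edge_degree)), c(16L, 8L, 1L))
  # the unique degree-3 cell is the lattice center
  center <- which(g$x_um == 20 & g$y_um == 20)
  expect_identical(ann$edge_degree[center], 3L)
})

test_that("angular-gap rule: hexagonal interior is center, grid corner and chain are edge", {
  # hexagonal packing: interior cell has 6 neighbors at 60 degree spacing
  hexa <- as.data.frame(popcontext:::.tri_lattice_disk(45, 10))
  names(hexa) <- c("x_um", "y_um")
  ann <- annotate_cells(hexa, annotation_params(eps = 12))
  origin <- which(hexa$x_um == 0 & hexa$y_um == 0)
  expect_false(ann$is_edge[origin])
  expect_identical(ann$position_class[origin], "center")

  g <- lattice(5, 5, 10)
  cl <- cluster_cells(g, annotation_params(eps = 15))
  edge <- classify_edge(g, cl, annotation_params(eps = 15))
  corner <- which(g$x_um == 0 & g$y_um == 0)
  expect_true(edge[corner])                  # max gap 270 degrees
  interior <- which(g$x_um == 20 & g$y_um == 20)
  expect_false(edge[interior])               # max gap 45 degrees

  chain <- data.frame(x_um = (0:9) * 10, y_um = 0)
  ann_c <- annotate_cells(chain, annotation_params(eps = 12))
  expect_true(all(ann_c$is_edge))            # max gap 180 degrees everywhere
  expect_true(all(ann_c$edge_degree == 1L))
})

test_that("micro-colonies below min_pts are edge cells of degree 1, not singles", {
  pair <- data.frame(x_um = c(0, 10, 200, 205, 210), y_um = 0)
  ann <- annotate_cells(pair, annotation_params(eps = 12, min_pts = 4))
  expect_identical(ann$position_class, rep("edge", 5))
  expect_identical(ann$edge_degree, rep(1L, 5))
  expect_identical(ann$cluster_id, c(1L, 1L, 2L, 2L, 2L))
})

test_that("coincident centroids are rejected", {
  dup <- data.frame(x_um = c(1, 1), y_um = c(2, 2))
  expect_error(annotate_cells(dup, annotation_params(eps = 5)), "oincident")
})

test_that("annotation invariants hold on random fields", {
  for (seed in 1:5) {
    f <- random_field(120, seed = seed)
    ann <- annotate_cells(f, annotation_params(eps = 25))
    # degree 0 <=> single <=> no neighbors
    expect_identical(ann$edge_degree == 0L, ann$position_class == "single")
    expect_identical(ann$edge_degree == 0L, ann$n_neighbors == 0L)
    # degree >= 2 => center
    expect_true(all(ann$position_class[ann$edge_degree >= 2L] == "center"))
    # within a cluster degrees are contiguous {1..d_max}
    for (cid in unique(na.omit(ann$cluster_id))) {
      dd <- sort(unique(ann$edge_degree[!is.na(ann$cluster_id) &
                                          ann$cluster_id == cid]))
      expect_identical(dd, seq_len(max(dd)))
    }
  }
})

test_that("annotation is invariant under rigid motions", {
  f <- random_field(100, seed = 7)
  p <- annotation_params(eps = 25)
  a0 <- annotate_cells(f, p)
  th <- 0.71
  rot <- data.frame(x_um = cos(th) * f$x_um - sin(th) * f$y_um + 311,
                    y_um = sin(th) * f$x_um + cos(th) * f$y_um - 97)
  a1 <- annotate_cells(rot, p)
  expect_identical(a0$edge_degree, a1$edge_degree)
  expect_identical(a0$is_edge, a1$is_edge)
  expect_identical(table(a0$cluster_id), table(a1$cluster_id))
})

test_that("pipeline output equals the brute-force oracle on lattices and random fields", {
  cases <- list(lattice(4, 4, 10), lattice(7, 3, 10), lattice(9, 9, 10))
  for (g in cases) {
    ann <- annotate_cells(g, annotation_params(eps = 15))
    orc <- oracle_annotate(g$x_um, g$y_um, eps = 15)
    expect_identical(ann$edge_degree, orc$degree)
    expect_identical(ann$is_edge, orc$is_edge)
    expect_identical(ann$cluster_id, orc$cluster)
  }
  for (seed in 1:10) {
    f <- random_field(80, seed = 100 + seed)
    ann <- annotate_cells(f, annotation_params(eps = 22))
    orc <- oracle_annotate(f$x_um, f$y_um, eps = 22)
    expect_identical(ann$edge_degree, orc$degree)
    expect_identical(ann$cluster_id, orc$cluster)
    expect_identical(ann$n_neighbors, orc$n_neighbors)
  }
})

test_that("the literal reference annotator matches the pipeline on mixed fields", {
  cfg <- generator_config(n_colonies = 3, colony_cells_dist = c(10, 25),
                          n_singles = 10, field_width_um = 1200,
                          field_height_um = 1200, seed = 17)
  f <- generate_colony_field(cfg)
  p <- annotation_params(eps = 1.5 * cfg$cell_spacing_um)
  ann <- annotate_cells(f, p)
  ref <- reference_annotation(f$cells, eps = p$eps)
  expect_identical(ann$edge_degree, ref$edge_degree)
  expect_identical(ann$cluster_id, ref$cluster_id)
  expect_identical(ann$position_class, ref$position_class)
})

test_that("ground-truth position classes are recovered on synthetic colonies", {
  cfg <- generator_config(n_colonies = 4, colony_cells_dist = c(25, 45),
                          n_singles = 25, field_width_um = 2200,
                          field_height_um = 2200, seed = 23)
  f <- generate_colony_field(cfg)
  ann <- annotate_cells(f, annotation_params(eps = 1.5 * cfg$cell_spacing_um))
  truth_single <- f$cells$true_is_single
  recovered <- (ann$position_class == "single") == truth_single
  expect_gte(mean(recovered), 0.95)
})

test_that("growing a disk colony never decreases its maximum edge degree", {
  cfg0 <- generator_config(cell_spacing_um = 12, seed = 2)
  maxdeg <- sapply(c(100, 160, 220), function(dia) {
    cfg <- cfg0; cfg$pattern_diameter_um <- dia
    f <- generate_micropattern_population(cfg)
    ann <- annotate_cells(f, annotation_params(eps = 1.5 * 12))
    max(ann$edge_degree)
  })
  expect_true(all(diff(maxdeg) >= 0))
})
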