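line_skel <- function(len = 100, n = 120) {
  m <- matrix(FALSE, n, n)
  m[60, 11:(10 + len)] <- TRUE
  m
}

# hand-built graph with controllable segment lengths
toy_graph <- function(lengths, total = sum(lengths)) {
  structure(list(nodes = integer(0),
                 n_branch_clusters = 0L,
                 segments = lapply(seq_along(lengths), function(i)
                   seq_len(lengths[i]) + 1000L * i),
                 lengths = as.numeric(lengths),
                 total_capillary_px = total,
                 dim = c(10000L, 10000L)),
            class = "skeleton_graph")
}

test_that("a straight line decomposes into two end nodes and one segment", {
  g <- skeleton_to_graph(line_skel(100))
  expect_equal(length(g$segments), 1L)
  expect_equal(length(g$nodes), 2L)
  expect_equal(g$total_capillary_px, 100)
  expect_gte(g$lengths[1], 98)
  expect_equal(g$n_branch_clusters, 0L)
})

test_that("a plus sign has one branch cluster and four segments", {
  m <- matrix(FALSE, 41, 41)
  m[21, 5:37] <- TRUE
  m[5:37, 21] <- TRUE
  g <- skeleton_to_graph(m)
  expect_equal(length(g$segments), 4L)
  expect_equal(g$n_branch_clusters, 1L)
  # segment pixels and node pixels partition the skeleton exactly
  seg_px <- unlist(g$segments)
  expect_equal(sort(c(seg_px, g$nodes)), which(m))
  expect_equal(anyDuplicated(c(seg_px, g$nodes)), 0L)
})

test_that("an empty raster yields an empty graph", {
  g <- skeleton_to_graph(matrix(FALSE, 20, 20))
  expect_equal(length(g$segments), 0L)
  expect_equal(length(g$nodes), 0L)
  expect_error(remove_segments_until(g, 10), "nothing to remove")
})

test_that("an isolated cycle becomes one segment with a break node", {
  d <- abs(outer(1:30 - 15, rep(0, 30), "+")) + abs(outer(rep(0, 30), 1:30 - 15, "+"))
  ring <- d == 8          # diamond: every pixel has exactly two diagonal neighbors
  g <- skeleton_to_graph(ring)
  expect_equal(length(g$segments), 1L)
  expect_equal(length(g$nodes), 1L)
  expect_equal(length(g$segments[[1]]) + 1L, sum(ring))
})

test_that("graph decomposition agrees with an igraph path oracle", {
  skip_if_not_installed("igraph")
  for (seed in 1:5) {
    sk <- cpp_thin(random_blobs(50, 50, p = 0.35, seed = seed + 10))
    g <- skeleton_to_graph(sk)
    # partition property
    seg_px <- unlist(g$segments)
    expect_equal(sort(c(seg_px, g$nodes)), which(sk))
    expect_equal(anyDuplicated(c(seg_px, g$nodes)), 0L)
    # oracle: segments = connected components of the degree-2 induced subgraph
    idx <- which(sk)
    nr <- nrow(sk)
    coord <- cbind((idx - 1L) %% nr, (idx - 1L) %/% nr)
    adj <- which(outer(coord[, 1], coord[, 1], function(a, b) abs(a - b)) <= 1 &
                 outer(coord[, 2], coord[, 2], function(a, b) abs(a - b)) <= 1,
                 arr.ind = TRUE)
    adj <- adj[adj[, 1] < adj[, 2], , drop = FALSE]
    gr <- igraph::graph_from_edgelist(cbind(adj), directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0, length(idx) - igraph::vcount(gr)))
    deg <- igraph::degree(gr)
    deg2 <- which(deg == 2)
    sub <- igraph::induced_subgraph(gr, deg2)
    comp <- igraph::components(sub)
    # non-cycle chains: every chain of degree-2 pixels is one segment; cycles
    # lose one pixel to the designated break node
    expect_equal(length(g$segments), comp$no)
    mine <- sort(vapply(g$segments, length, 0L))
    oracle <- sort(comp$csize)
    expect_true(all(abs(mine - oracle) <= 1))   # cycles lose one break pixel
    expect_gte(sum(oracle), sum(mine))
  }
})

test_that("removal stops when the intended loss is just exceeded", {
  g <- toy_graph(rep(1, 100))
  r <- remove_segments_until(g, 10, seed = 1)
  expect_equal(length(r$removed_segment_ids), 11L)   # strict exceedance
  expect_equal(r$actual_pct, 11)
  r0 <- remove_segments_until(g, 0, seed = 1)
  expect_equal(length(r0$removed_segment_ids), 0L)
  expect_equal(r0$actual_pct, 0)
  # >= variant stops one earlier on exact ties
  rg <- remove_segments_until(g, 10, seed = 1, exceed = "gte")
  expect_equal(length(rg$removed_segment_ids), 10L)
})

test_that("unreachable intended loss removes every segment", {
  g <- toy_graph(rep(2, 10), total = 25)   # 5 px live in nodes
  r <- remove_segments_until(g, 100, seed = 2)
  expect_equal(sort(r$removed_segment_ids), 1:10)
  expect_equal(r$actual_pct, 100 * 20 / 25)
})

test_that("strict exceedance and the overshoot bound hold on a real skeleton", {
  sp <- small_specimen(seed = 6)
  g <- skeleton_to_graph(as_vessel_segmentation(sp)$capillary_skeleton)
  bound <- 100 * max(g$lengths) / g$total_capillary_px
  for (lev in c(1, 7, 23, 50)) for (s in 1:5) {
    r <- remove_segments_until(g, lev, seed = s * 101 + lev)
    expect_gt(r$actual_pct, lev)
    expect_lte(r$actual_pct, lev + bound)
  }
})

test_that("rebuilding without removals is the canonical baseline image", {
  sp <- small_specimen(seed = 4)
  seg <- as_vessel_segmentation(sp)
  base <- rebuild_binary(seg$full_skeleton, integer(0), seg$large_mask,
                         seg$dilate_radius)
  expect_identical(base, cpp_dilate_disk(seg$full_skeleton, seg$dilate_radius) |
                           seg$large_mask)
})

test_that("removing a far isolated segment shrinks the foreground accordingly", {
  m <- line_skel(60)
  m[20, 5:34] <- TRUE                 # separate 30-px line
  mask <- matrix(FALSE, 120, 120)
  g <- skeleton_to_graph(m)
  iso <- which(vapply(g$segments, function(s)
    all(((s - 1L) %% 120 + 1L) == 20), TRUE))
  full <- rebuild_binary(m, integer(0), mask, 5L)
  rem <- rebuild_binary(m, g$segments[[iso]], mask, 5L)
  expect_gte(sum(full) - sum(rem), length(g$segments[[iso]]))
})

test_that("removing everything leaves the dilated nodes plus the mask", {
  m <- line_skel(60)
  g <- skeleton_to_graph(m)
  mask <- matrix(FALSE, 120, 120); mask[100:110, 100:110] <- TRUE
  out <- rebuild_binary(m, unlist(g$segments), mask, 5L)
  nodes <- matrix(FALSE, 120, 120); nodes[g$nodes] <- TRUE
  expect_identical(out, cpp_dilate_disk(nodes, 5L) | mask)
})

test_that("rebuilding checks pixel provenance and dimensions", {
  m <- line_skel(20)
  expect_error(rebuild_binary(m, which(!m)[1], matrix(FALSE, 120, 120), 5L),
               "subset")
  expect_error(rebuild_binary(m, integer(0), matrix(FALSE, 10, 10), 5L),
               "dimension")
})

test_that("vessel density is non-increasing along nested removals", {
  sp <- small_specimen(seed = 8)
  seg <- as_vessel_segmentation(sp)
  g <- skeleton_to_graph(seg$capillary_skeleton)
  set.seed(99)
  perm <- sample.int(length(g$segments))
  vd_prev <- Inf
  for (k in c(0, 50, 200, 500, length(perm))) {
    px <- if (k == 0) integer(0) else
      unlist(g$segments[perm[seq_len(k)]], use.names = FALSE)
    vd <- mean(rebuild_binary(seg$full_skeleton, px, seg$large_mask,
                              seg$dilate_radius))
    expect_lte(vd, vd_prev)
    vd_prev <- vd
  }
})

test_that("the sweep enumerates levels x iterations and is reproducible", {
  sp <- small_specimen(seed = 14)
  seg <- as_vessel_segmentation(sp)
  cfg <- sweep_config(pct_min = 10, pct_max = 20, pct_step = 10, n_iter = 3,
                      master_seed = 77)
  sw1 <- run_sweep(seg, cfg, small_pica(), specimen_id = "a")
  expect_equal(nrow(sw1$trials), 6L)
  sw2 <- run_sweep(seg, cfg, small_pica(), specimen_id = "a")
  expect_identical(sw1$trials, sw2$trials)
  expect_true(all(sw1$trials$actual_pct > sw1$trials$intended_pct))
  # mean overshoot is small and level-independent to first order
  os <- tapply(sw1$trials$actual_pct - sw1$trials$intended_pct,
               sw1$trials$intended_pct, mean)
  expect_lt(max(os), 1)
})

test_that("the full design enumerates 4.7 million simulated images", {
  expect_equal(sweep_plan(94, sweep_config()), 4700000)
  expect_equal(sweep_plan(1, sweep_config(pct_min = 5, pct_max = 10,
                                          pct_step = 5, n_iter = 7)), 14)
})
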