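test_that("neuron placement is an offset equidistant grid", {
  set.seed(1)
  lay <- place_neurons(100, offset_scale = 1e-3)
  expect_equal(lay$n, 100)
  spacing <- diff(lay$coords)
  expect_equal(mean(spacing), 1 / 99, tolerance = 1e-3)
  grid <- seq(-0.5, 0.5, length.out = 100)
  off <- lay$coords - grid
  expect_true(all(off >= 0 & off <= 1e-3))
  expect_false(is.unsorted(lay$coords))
  expect_error(place_neurons(1), ">= 2")
})

test_that("N-network wiring matches brute-force nearest-neighbour
           enumeration on small instances", {
  set.seed(5)
  for (rep in 1:5) {
    pre <- place_neurons(sample(5:15, 1), offset_scale = 1e-3)
    post <- place_neurons(sample(8:20, 1), offset_scale = 1e-3)
    n_out <- sample(1:4, 1)
    g <- build_n_network(pre, post, n_out)
    for (i in seq_len(pre$n)) {
      got <- sort(g$post[g$pre == i])
      want <- sort(brute_force_nearest(pre$coords[i], post$coords, n_out))
      expect_identical(got, want)
    }
  }
  # recurrent wiring never self-connects
  set.seed(6)
  lay <- place_neurons(12, offset_scale = 1e-3)
  g <- build_n_network(lay, lay, 3, exclude_self = TRUE)
  expect_true(all(g$pre != g$post))
  expect_error(build_n_network(lay, lay, 13), "exceeds")
})

test_that("D-network displaces exactly round(P * n_edges) edges towards the
           shifted coordinate", {
  set.seed(7)
  pre <- place_neurons(100, offset_scale = 1e-3)
  post <- place_neurons(300, offset_scale = 1e-3)
  base <- build_n_network(pre, post, 3)
  d <- 0.15
  g <- build_d_network(base, pre, post, P = 0.1, d = d)
  expect_equal(sum(g$displaced), round(0.1 * nrow(base)))
  expect_identical(g[!g$displaced, c("pre", "post")],
                   base[!g$displaced, c("pre", "post")])
  # displaced edges concentrate at the displacement within one post spacing;
  # sources whose shifted target falls past the axis end clamp to the
  # outermost neurons and are checked separately
  shift <- post$coords[g$post[g$displaced]] - pre$coords[g$pre[g$displaced]]
  interior <- pre$coords[g$pre[g$displaced]] + d <= max(post$coords)
  expect_gt(sum(interior), 0)
  expect_lt(max(abs(shift[interior] - d)), 1 / 299 + 2e-3)
  if (any(!interior))
    expect_true(all(post$coords[g$post[g$displaced][!interior]] >
                      max(post$coords) - 0.05))
  # degenerate settings collapse to the identity / N-network
  expect_identical(build_d_network(base, pre, post, P = 0), base)
  g0 <- build_d_network(base, pre, post, P = 1, d = 0)
  expect_equal(sort(unique(g0$post[g0$pre == 50])),
               sort(base$post[base$pre == 50]))
})

test_that("S-network skips every second postsynaptic neuron and doubles the
           projection span", {
  set.seed(8)
  pre <- place_neurons(11, offset_scale = 1e-4)
  post <- place_neurons(11, offset_scale = 1e-4)
  g <- build_s_network(pre, post, 3)
  # centre neuron targets index offsets {0, +-2}
  centre <- 6
  expect_setequal(g$post[g$pre == centre], c(centre, centre - 2, centre + 2))
  # out-degree 1 reduces to the N-network
  gn <- build_n_network(pre, post, 1)
  gs <- build_s_network(pre, post, 1)
  expect_identical(gs$post, gn$post)
  # span comparison on a longer grid
  set.seed(9)
  pre2 <- place_neurons(100, offset_scale = 1e-3)
  post2 <- place_neurons(100, offset_scale = 1e-3)
  span <- function(g, i) diff(range(post2$coords[g$post[g$pre == i]]))
  gN <- build_n_network(pre2, post2, 5)
  gS <- build_s_network(pre2, post2, 5)
  spans <- vapply(40:60, function(i) span(gS, i) / span(gN, i), 0)
  expect_equal(mean(spans), 2, tolerance = 0.15)
})

test_that("graph validation checks degrees, duplicates and self-loops", {
  set.seed(10)
  pre <- place_neurons(20, offset_scale = 1e-3)
  post <- place_neurons(30, offset_scale = 1e-3)
  g <- build_n_network(pre, post, 2)
  rep <- validate_graph(g, 20, 30, 2)
  expect_true(rep$ok)
  expect_equal(sum(rep$in_degree), nrow(g))
  bad <- g
  bad$post[1] <- bad$post[2]
  expect_false(validate_graph(bad, 20, 30, 2)$ok)
})

test_that("edge counts conserve the configured out-degree in every network
           type of the full circuit", {
  for (type in c("N", "D", "S")) {
    circ <- build_circuit(network = type, seed = 4)
    for (nm in names(circ$graphs)) {
      p <- circ$projections[[nm]]
      n_pre <- circ$layouts[[p$src]]$n
      expect_equal(nrow(circ$graphs[[nm]]), n_pre * p$N_out)
    }
  }
})

test_that("circuit construction is reproducible from its seed", {
  c1 <- build_circuit(network = "D", seed = 11)
  c2 <- build_circuit(network = "D", seed = 11)
  expect_identical(c1$graphs, c2$graphs)
  expect_identical(c1$layouts, c2$layouts)
  c3 <- build_circuit(network = "D", seed = 12)
  expect_false(identical(c1$graphs$stn_gpe, c3$graphs$stn_gpe))
})
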