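# shared test fixtures, built in code

# small random connected weighted graph (Erdos-Renyi + spanning chain)
rand_graph <- function(n, p = 0.5, seed = 1) {
  set.seed(seed)
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  on <- up[stats::runif(length(up)) < p]
  a[on] <- stats::runif(length(on), 0.2, 2)
  a <- a + t(a)
  for (i in seq_len(n - 1)) if (a[i, i + 1] == 0)
    a[i, i + 1] <- a[i + 1, i] <- stats::runif(1, 0.2, 2)
  connectome(a)
}

fx <- fixture_graphs()

edge_multiset <- function(g) sort(connectome_edges(g)$weight)
degree_seq <- function(g) unname(rowSums(g$adjacency > 0))

expect_simple_graph <- function(g) {
  expect_true(max(abs(g$adjacency - t(g$adjacency))) < 1e-12)
  expect_true(all(diag(g$adjacency) == 0))
  expect_true(all(g$adjacency >= 0))
}
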