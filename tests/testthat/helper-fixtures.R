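# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except the packaged registry.

path_graph <- function(n, ids = sprintf("P%02d", seq_len(n))) {
  adjacency_graph(ids, cbind(ids[-n], ids[-1]))
}

# graph made of k disjoint edges (2-node components); cheap way to get many
# areas without a large eigendecomposition
pair_graph <- function(k) {
  ids <- sprintf("A%05d", seq_len(2 * k))
  adjacency_graph(ids, cbind(ids[seq(1, 2 * k, 2)], ids[seq(2, 2 * k, 2)]))
}

# a small complete model frame on a given graph, generated from the model
make_test_frame <- function(graph, years = 2014:2019, population = 50000,
                            config = list(beta0 = log(5), beta3 = 0.05,
                                          sigma = 0.5, rho = 0.7),
                            seed = 1L) {
  truth <- gen_truth(graph, config, seed = seed)
  frame <- gen_area_year_counts(truth, graph, years, population,
                                seed = seed + 1L)
  frame$RATE <- frame$Y / frame$E
  class(frame) <- c("model_frame", "data.frame")
  attr(frame, "truth") <- truth
  frame
}

quick_sampler <- list(chains = 2, iter_warmup = 200, iter_sampling = 200)

# random simple graph on <= max_n nodes with at least one edge
random_small_graph <- function(max_n = 12, seed = NULL) {
  n <- sample(2:max_n, 1)
  ids <- sprintf("N%02d", seq_len(n))
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < 0.4
  if (!any(keep)) keep[sample(nrow(pairs), 1)] <- TRUE
  adjacency_graph(ids, pairs[keep, , drop = FALSE])
}
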