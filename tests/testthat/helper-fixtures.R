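# Small fixtures shared across test files; everything built in code.

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

toy_table <- function() {
  m <- matrix(c(5, 0, 1, 2, 0, 7), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  storage.mode(m) <- "double"
  m
}

# small two-season metacommunity, cached per session
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_taxa = 120, n_reaches = 4, n_replicates = 3,
                        lib_meanlog = log(1200), lib_sdlog = 0.2,
                        lib_min = 600, lib_max = 3000, seed = 42)
      cache <<- simulate_metacommunity(cfg)
    }
    cache
  }
})

rand_counts <- function(n_otu, n_sample, seed, lambda = 8) {
  set.seed(seed)
  m <- matrix(rpois(n_otu * n_sample, lambda), n_otu, n_sample,
              dimnames = list(sprintf("o%03d", seq_len(n_otu)),
                              sprintf("s%03d", seq_len(n_sample))))
  storage.mode(m) <- "double"
  m
}
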