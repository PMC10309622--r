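# Shared fixtures, built in code.  The cat-like network is memoized since
# several files exercise it.

.fixtures <- new.env(parent = emptyenv())

cat_fixture <- function() {
  if (is.null(.fixtures$cat)) {
    nw <- build_parallel_coil_network()
    .fixtures$cat <- list(network = nw,
                          flow = solve_network_flow(nw))
  }
  .fixtures$cat
}

ref_odorant <- function(beta = 1) {
  odorant("reference", 127, 117, beta = beta, Da = 6e-6, Dm = 1e-9,
          quiet = TRUE)
}

# two parallel segments between the same junctions
make_parallel_pair <- function(lengths = c(0.05, 0.05), width = 1e-3) {
  seg <- channel_segments(c("b1", "b2"), "naris", "pharynx", lengths, width,
                          region = "posterior_respiratory",
                          epithelium = "respiratory")
  nasal_network(seg, "naris", "pharynx")
}

# serial chain: anterior -> olfactory (dorsal-medial label so the olfactory
# region is present without coils)
make_serial_chain <- function(l_ant = 0.02, l_olf = 0.05, width = 1e-3) {
  seg <- rbind(
    channel_segments("ant", "naris", "j", l_ant, width,
                     region = "anterior_respiratory",
                     epithelium = "respiratory"),
    channel_segments("olf", "j", "pharynx", l_olf, width,
                     region = "dorsal_medial", epithelium = "olfactory")
  )
  nasal_network(seg, "naris", "pharynx")
}

# anterior trunk splitting into an olfactory and a posterior branch
make_toy_three <- function(l_ant = 0.02, l_olf = 0.05, l_post = 0.03,
                           w_ant = 2e-3, w_olf = 8e-4, w_post = 1e-3) {
  seg <- rbind(
    channel_segments("ant", "naris", "j", l_ant, w_ant,
                     region = "anterior_respiratory",
                     epithelium = "respiratory"),
    channel_segments("olf", "j", "pharynx", l_olf, w_olf,
                     region = "dorsal_medial", epithelium = "olfactory"),
    channel_segments("post", "j", "pharynx", l_post, w_post,
                     region = "posterior_respiratory",
                     epithelium = "respiratory")
  )
  nasal_network(seg, "naris", "pharynx")
}

# small randomized parallel-coil network for property tests
random_coil_network <- function(seed) {
  pars <- with_seed_test(seed, list(
    n_coils = sample(2:12, 1),
    coil_path_length = runif(1, 0.02, 0.2),
    coil_width = runif(1, 2e-4, 1e-3),
    dm_length = runif(1, 0.005, 0.05),
    dm_width = runif(1, 1e-3, 3e-3),
    bank_n = sample(3:30, 1),
    bank_width = runif(1, 2e-4, 1e-3),
    post_n = sample(2:20, 1),
    post_width = runif(1, 3e-4, 2e-3)
  ))
  build_parallel_coil_network(
    n_coils = pars$n_coils, coil_path_length = pars$coil_path_length,
    coil_width = pars$coil_width, dm_length = pars$dm_length,
    dm_width = pars$dm_width,
    anterior_spec = list(trunk_length = 0.004, trunk_width = 3e-3,
                         dm_passage_length = 0.02, dm_passage_width = 2e-3,
                         bank_n = pars$bank_n, bank_length = 0.02,
                         bank_width = pars$bank_width),
    posterior_spec = list(bank_n = pars$post_n, bank_length = 0.08,
                          bank_width = pars$post_width,
                          nasopharynx_length = 0.03,
                          nasopharynx_width = 4e-3),
    seed = seed)
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}
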