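# Study-design fixture: 12 individual trees plus 4 grouped (3-tree) datasets
# spanning 2019-2023, mirroring the individual/urban/non-urban x species
# dataset layout the benchmark harness is designed around. Onset steepness
# and amplitude vary across trees; grouped datasets train on an hourly grid
# (thin = 2) like multi-tree datasets are conventionally resampled.

build_study_datasets <- function(seed = 1L, years = 2019:2023,
                                 n_individual = 12L, n_grouped = 4L) {
  datasets <- list()
  for (i in seq_len(n_individual)) {
    p <- sim_params(years = years,
                    amplitude_um = 400 + 40 * (i %% 5),
                    onset_doy = 125 + 4 * (i %% 4),
                    cessation_doy = 245 + 4 * (i %% 3),
                    steepness = c(0.08, 0.1, 0.2, 0.35)[1 + (i %% 4)],
                    species = c("maple", "plane")[1 + (i %% 2)],
                    environment = c("urban", "non-urban")[1 + (i %/% 7)],
                    seed = seed + i)
    tr <- simulate_tree(p, sprintf("ind%02d", i))
    g <- winter_correction(zero_growth(tr$dendro))
    datasets[[sprintf("ind%02d", i)]] <-
      list(growth = g, truth = g, meta = tr$meta)
  }
  groups <- expand.grid(species = c("maple", "plane"),
                        environment = c("urban", "non-urban"),
                        stringsAsFactors = FALSE)[seq_len(n_grouped), ]
  for (j in seq_len(n_grouped)) {
    p <- sim_params(years = years, species = groups$species[j],
                    environment = groups$environment[j],
                    seed = seed + 100L + j)
    net <- simulate_network(3, rho = 0.8, p)
    gs <- lapply(net, function(b) winter_correction(zero_growth(b$dendro)))
    meta <- do.call(rbind, lapply(net, function(b) as.data.frame(b$meta)))
    datasets[[sprintf("grp_%s_%s", groups$environment[j],
                      groups$species[j])]] <-
      list(growth = gs, truth = gs, meta = meta, thin = 2L)
  }
  datasets
}
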