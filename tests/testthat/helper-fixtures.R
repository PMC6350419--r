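# Small programmatic fixtures shared across test files.

# A tiny generated cohort (default 10 regions) with its ground truth.
small_cohort <- function(seed = 1, n_pairs = 5, n_core = 14, noise_sd = 1,
                         extras = 3, n_subjects = 12) {
  generate_nki_like_cohort(
    generator_config(n_region_pairs = n_pairs, n_core_links = n_core,
                     n_extra_links_per_subject = extras, noise_sd = noise_sd,
                     rng_seed = seed),
    n_subjects = n_subjects)
}

# A hand-built valid connectome on n regions from an explicit matrix.
toy_connectome <- function(W, id = "toy", age = 60, sex = 1,
                           group = "healthy") {
  connectome(id, age, sex, group, W)
}

# Symmetrize an upper-triangle specification.
sym <- function(W) {
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  diag(W) <- 0
  W
}

# An aging fit with explicitly chosen coefficients on given links
# (list of c(i, j, b0, b1, b2, b3, b4), 0-based indices).
manual_aging_fit <- function(n_regions, links) {
  mask <- matrix(FALSE, n_regions, n_regions)
  rows <- lapply(links, function(l) {
    mask[l[1] + 1, l[2] + 1] <<- TRUE
    mask[l[2] + 1, l[1] + 1] <<- TRUE
    tibble::tibble(i = as.integer(l[1]), j = as.integer(l[2]), b0 = l[3],
                   b1 = l[4], b2 = l[5], b3 = l[6], b4 = l[7],
                   inc_age = l[4] != 0, inc_sex = l[5] != 0,
                   inc_agesex = l[6] != 0, inc_age2 = l[7] != 0,
                   criterion_value = NA_real_)
  })
  structure(list(
    grid = structure(list(mask = mask,
                          link_list = dplyr::bind_rows(rows)[, c("i", "j")]),
                     class = "grid_mask"),
    models = dplyr::bind_rows(rows), criterion = "manual",
    n_regions = n_regions), class = "aging_fit")
}

null_fit <- function(n) adspread:::null_aging_fit(n)
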