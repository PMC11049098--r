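# fixture builders used across the suite

make_food_table <- function(product_name, ingredient_text = NA_character_,
                            category = "Test", subcategory = "Test",
                            physical_state = "solid",
                            energy_kj = 500, energy_kcal = NA_real_,
                            protein_g = 5, sfa_g = 1, sugars_g = 5,
                            sodium_mg = 100, fiber_g = 1,
                            fv_percent = NA_real_) {
  n <- length(product_name)
  suppressWarnings(validate_food_table(tibble::tibble(
    record_id = paste0("r", seq_len(n)),
    product_name = product_name,
    long_name = NA_character_,
    category = rep_len(category, n),
    subcategory = rep_len(subcategory, n),
    physical_state = rep_len(physical_state, n),
    ingredient_text = rep_len(ingredient_text, n),
    energy_kj = rep_len(energy_kj, n),
    energy_kcal = rep_len(energy_kcal, n),
    protein_g = rep_len(protein_g, n),
    sfa_g = rep_len(sfa_g, n),
    sugars_g = rep_len(sugars_g, n),
    sodium_mg = rep_len(sodium_mg, n),
    fiber_g = rep_len(fiber_g, n),
    fv_percent = rep_len(fv_percent, n)
  )))
}

# a random nutrient panel tibble for property tests
random_panels <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    energy_kj = runif(n, 0, 4000),
    sugars_g = runif(n, 0, 60),
    sfa_g = runif(n, 0, 15),
    sodium_mg = runif(n, 0, 1200),
    protein_g = runif(n, 0, 15),
    fiber_g = runif(n, 0, 8),
    fv_percent = runif(n, 0, 100)
  ))
}

score_panel <- function(p, preset = "paper", state = "solid") {
  pts <- dplyr::bind_cols(
    negative_points(p$energy_kj, p$sugars_g, p$sfa_g, p$sodium_mg,
                    preset = preset, physical_state = state),
    positive_points(p$protein_g, p$fiber_g, p$fv_percent,
                    preset = preset, physical_state = state)
  )
  fsam_nps(pts, preset = preset)
}

# brute-force Mann-Whitney U (pair counting, ties count 1/2)
brute_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# exact two-sided MWU p by enumeration of all group assignments
brute_mwu_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(k) brute_u(pooled[k], pooled[-k]))
  u_obs <- brute_u(x, y)
  mu <- n1 * (length(pooled) - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# hand Pearson chi-square statistic
hand_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}
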