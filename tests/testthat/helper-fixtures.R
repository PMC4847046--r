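# shared fixture builders (everything generated in code)

random_sample_set <- function(n, seed, extent = 100, analyte = "Cu",
                              lognormal = TRUE) {
  set.seed(seed)
  v <- if (lognormal) exp(rnorm(n, 5, 1)) else runif(n, 10, 100)
  sample_set(paste0("r", seq_len(n)),
             runif(n, 0, extent), runif(n, 0, extent), v, analyte = analyte)
}

# bundled 23-sample lab assay table, one row per sample (wide on analyte)
assay_table <- function() {
  df <- utils::read.csv(example_assay_path())
  cu <- df[df$analyte == "Cu", ]
  pb <- df[df$analyte == "Pb", ]
  data.frame(id = cu$id, x = cu$x, y = cu$y, cu = cu$value,
             pb = pb$value[match(cu$id, pb$id)], ec = cu$ec, ph = cu$ph,
             role = cu$role)
}

# a random valid LMC (shared gaussian structure, Cauchy-Schwarz satisfied)
random_lmc <- function(seed) {
  set.seed(seed)
  rng <- runif(1, 30, 80)
  ratio <- runif(1, 0.5, 1)
  az <- runif(1, 0, 180)
  p1 <- runif(1, 0.5, 3); p2 <- runif(1, 0.5, 3)
  rho <- runif(1, 0.3, 0.9)
  n1 <- runif(1, 0.05, 0.3); n2 <- runif(1, 0.05, 0.3)
  cross_variogram_model(
    variogram_model("gaussian", n1, p1, rng, rng * ratio, az,
                    sill_is_total = FALSE),
    variogram_model("gaussian", n2, p2, rng, rng * ratio, az,
                    sill_is_total = FALSE),
    variogram_model("gaussian", 0, rho * sqrt(p1 * p2), rng, rng * ratio, az,
                    sill_is_total = FALSE))
}

gamma_fun_of <- function(model) function(dx, dy) model_gamma(model, dx, dy)
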