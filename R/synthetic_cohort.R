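#' Configuration of the synthetic cohort generator
#'
#' Collects the generative parameters of a seeded synthetic cohort whose
#' statistical structure mirrors what the composite-risk analysis assumes:
#' sex-specific baseline disease prevalence (higher in males), a monotone
#' raw-PRS effect, a monotone BMI effect, a U-shaped birth-weight effect with
#' low weight the stronger risk, a three-category childhood body-size effect
#' (plumper > thinner > average) and prevalence increasing with age over
#' 40--70.  Disease status is drawn from a logistic liability model
#' \deqn{\mathrm{logit}\,p = \mathrm{logit}(\pi_{sex}) + \beta_{prs} z_{prs}
#'   + \beta_{bmi} z_{bmi} + \beta_{bw,1} z_{bw} + \beta_{bw,2} z_{bw}^2
#'   + \delta_{bodysize} + \beta_{age}(age - 55)}
#' where the z's are the standardized covariates.
#'
#' Marginal distributions are stand-ins (the quantities of interest are
#' directions and monotonicity, not marginals): raw PRS is standard normal,
#' birth weight normal with mean 3.3 kg and SD 0.5 kg, BMI lognormal with
#' median ~27, body-size categories drawn with probabilities (0.3, 0.5, 0.2)
#' for (thinner, average, plumper).  All are overridable here.
#'
#' @param n_individuals cohort size; at least 200 so that 100 quantile bins
#'   stay populated in a 70 percent training split.
#' @param sex_ratio fraction female in \[0, 1\].
#' @param base_prevalence_male,base_prevalence_female disease probability at
#'   the covariate means and age 55, per sex; both in (0, 1).
#' @param beta_prs,beta_bmi log-odds per SD of the raw PRS / of log-BMI.
#' @param beta_bw_linear,beta_bw_quad log-odds coefficients on standardized
#'   birth weight and its square; `beta_bw_quad > 0` with
#'   `beta_bw_linear < 0` gives the low-weight-dominant U shape.
#' @param bodysize_logodds named numeric log-odds offsets for exactly the
#'   categories `thinner`, `average`, `plumper`.
#' @param beta_age log-odds per year of age, centred at the age midpoint.
#' @param age_range integer bounds, inclusive, within \[40, 70\].
#' @param n_markers number of markers for [generate_genotypes()].
#' @param allele_freq_range effect-allele frequency bounds in (0, 1).
#' @param bodysize_probs sampling probabilities of the three categories.
#' @param bmi_meanlog,bmi_sdlog lognormal parameters of BMI (kg/m^2).
#' @param bw_mean,bw_sd birth weight mean and SD (kg).
#' @param kinship_rate fraction of individuals placed into 2-member kinship
#'   groups (labels only; no genetic sharing is simulated).
#' @param seed integer seed; fully determines the generated cohort.
#' @return An object of class `simulation_config` (a validated list).
#' @seealso [generate_cohort()], [generate_genotypes()]
#' @export
simulation_config <- function(n_individuals,
                              sex_ratio = 0.54,
                              base_prevalence_male = 0.06,
                              base_prevalence_female = 0.04,
                              beta_prs = 0.4,
                              beta_bmi = 0.8,
                              beta_bw_linear = -0.3,
                              beta_bw_quad = 0.15,
                              bodysize_logodds = c(thinner = 0.15, average = 0,
                                                   plumper = 0.4),
                              beta_age = 0.04,
                              age_range = c(40L, 70L),
                              n_markers = 100L,
                              allele_freq_range = c(0.05, 0.95),
                              bodysize_probs = c(thinner = 0.3, average = 0.5,
                                                 plumper = 0.2),
                              bmi_meanlog = log(27),
                              bmi_sdlog = 0.15,
                              bw_mean = 3.3,
                              bw_sd = 0.5,
                              kinship_rate = 0,
                              seed = 1L) {
  prob_ok <- function(p) is.numeric(p) && length(p) == 1L && p > 0 && p < 1
  if (!is.numeric(n_individuals) || n_individuals < 200)
    stop("n_individuals must be >= 200 (100 bins must stay populated in a 70% training split)",
         call. = FALSE)
  if (!is.numeric(sex_ratio) || sex_ratio < 0 || sex_ratio > 1)
    stop("sex_ratio must lie in [0, 1]", call. = FALSE)
  if (!prob_ok(base_prevalence_male) || !prob_ok(base_prevalence_female))
    stop("base prevalences must lie strictly in (0, 1)", call. = FALSE)
  if (length(age_range) != 2L || age_range[1] > age_range[2] ||
      age_range[1] < 40 || age_range[2] > 70)
    stop("age_range must be a nonempty integer range within [40, 70]", call. = FALSE)
  if (length(allele_freq_range) != 2L || allele_freq_range[1] > allele_freq_range[2] ||
      allele_freq_range[1] <= 0 || allele_freq_range[2] >= 1)
    stop("allele_freq_range bounds must lie strictly in (0, 1)", call. = FALSE)
  lv <- c("thinner", "average", "plumper")
  if (!setequal(names(bodysize_logodds), lv) || !setequal(names(bodysize_probs), lv))
    stop("bodysize_logodds and bodysize_probs must be named with exactly: ",
         paste(lv, collapse = ", "), call. = FALSE)
  if (!is.numeric(n_markers) || n_markers < 1)
    stop("n_markers must be >= 1", call. = FALSE)
  if (kinship_rate < 0 || kinship_rate > 1)
    stop("kinship_rate must lie in [0, 1]", call. = FALSE)
  structure(list(
    n_individuals = as.integer(n_individuals), sex_ratio = sex_ratio,
    base_prevalence_male = base_prevalence_male,
    base_prevalence_female = base_prevalence_female,
    beta_prs = beta_prs, beta_bmi = beta_bmi,
    beta_bw_linear = beta_bw_linear, beta_bw_quad = beta_bw_quad,
    bodysize_logodds = bodysize_logodds[lv], beta_age = beta_age,
    age_range = as.integer(age_range), n_markers = as.integer(n_markers),
    allele_freq_range = allele_freq_range, bodysize_probs = bodysize_probs[lv],
    bmi_meanlog = bmi_meanlog, bmi_sdlog = bmi_sdlog,
    bw_mean = bw_mean, bw_sd = bw_sd,
    kinship_rate = kinship_rate, seed = as.integer(seed)),
    class = "simulation_config")
}

#' Generate a synthetic cohort table
#'
#' Draws one individual per row with sex, integer age, raw PRS, BMI, birth
#' weight, childhood body-size category, and Bernoulli disease status from
#' the logistic liability model described in [simulation_config()].  The
#' same configuration (including its seed) always yields an identical table.
#'
#' @param config a [simulation_config()] object.
#' @return A `data.frame` with columns `id`, `sex`, `age`, `raw_prs`, `bmi`,
#'   `birth_weight`, `body_size_age10`, `t2d` and, when
#'   `kinship_rate > 0`, `kinship_group` (NA outside groups).  The config is
#'   attached as attribute `"config"`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_individuals
  with_seed(config$seed, {
    sex <- ifelse(runif(n) < config$sex_ratio, "female", "male")
    age <- sample(seq.int(config$age_range[1], config$age_range[2]), n,
                  replace = TRUE)
    z_prs <- rnorm(n)
    bmi <- rlnorm(n, config$bmi_meanlog, config$bmi_sdlog)
    z_bmi <- (log(bmi) - config$bmi_meanlog) / config$bmi_sdlog
    bw <- rnorm(n, config$bw_mean, config$bw_sd)
    z_bw <- (bw - config$bw_mean) / config$bw_sd
    bs <- sample(names(config$bodysize_probs), n, replace = TRUE,
                 prob = config$bodysize_probs)
    base <- ifelse(sex == "female",
                   qlogis(config$base_prevalence_female),
                   qlogis(config$base_prevalence_male))
    mid <- mean(config$age_range)
    eta <- base +
      config$beta_prs * z_prs +
      config$beta_bmi * z_bmi +
      config$beta_bw_linear * z_bw +
      config$beta_bw_quad * z_bw^2 +
      unname(config$bodysize_logodds[bs]) +
      config$beta_age * (age - mid)
    t2d <- rbinom(n, 1L, plogis(eta))
    out <- data.frame(
      id = sprintf("ind%07d", seq_len(n)),
      sex = sex, age = as.integer(age),
      raw_prs = z_prs, bmi = bmi, birth_weight = bw,
      body_size_age10 = bs, t2d = as.integer(t2d),
      stringsAsFactors = FALSE)
    if (config$kinship_rate > 0) {
      n_grouped <- 2L * (floor(n * config$kinship_rate) %/% 2L)
      kin <- rep(NA_character_, n)
      if (n_grouped >= 2L) {
        members <- sample.int(n, n_grouped)
        kin[members] <- rep(sprintf("kin%05d", seq_len(n_grouped %/% 2L)),
                            each = 2L)
      }
      out$kinship_group <- kin
    }
    attr(out, "config") <- config
    out
  })
}

#' Generate synthetic genotype dosages with marker weights
#'
#' Draws per-marker effect-allele frequencies uniformly inside
#' `allele_freq_range`, dosages in \{0, 1, 2\} as binomial(2, freq), and
#' marker weights iid standard normal; the implied raw PRS of each
#' individual is the weighted dosage sum, enabling exact round-trip testing
#' of [compute_raw_prs()].
#'
#' @param config a [simulation_config()] object (`n_individuals`,
#'   `n_markers`, `allele_freq_range` and `seed` are used).
#' @return A list with `dosages` (n x m integer matrix, dimnames set),
#'   `weights` (data.frame `marker_id`, `effect_allele`, `weight`) and
#'   `raw_prs` (named numeric, the implied scores).
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_individuals
  m <- config$n_markers
  with_seed(config$seed, {
    freq <- runif(m, config$allele_freq_range[1], config$allele_freq_range[2])
    dos <- matrix(rbinom(n * m, 2L, rep(freq, each = n)), nrow = n,
                  dimnames = list(sprintf("ind%07d", seq_len(n)),
                                  sprintf("m%06d", seq_len(m))))
    wt <- data.frame(
      marker_id = colnames(dos),
      effect_allele = sample(c("A", "C", "G", "T"), m, replace = TRUE),
      weight = rnorm(m),
      stringsAsFactors = FALSE)
    prs <- drop(dos %*% wt$weight)
    list(dosages = dos, weights = wt, raw_prs = prs)
  })
}

#' Read or write a cohort table as tab-delimited text
#'
#' The on-disk format is a one-line header with the field names of the
#' cohort table (`id`, `sex`, `age`, `raw_prs`, `bmi`, `birth_weight`,
#' `body_size_age10`, `t2d`, optional `kinship_group`), tab separated;
#' optional fields absent from the data are simply omitted.
#'
#' @param cohort a cohort `data.frame`.
#' @param path file path.
#' @return `read_cohort` returns the cohort `data.frame`; `write_cohort`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("cohort file lacks an 'id' column", call. = FALSE)
  df$id <- as.character(df$id)
  df
}
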