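#' Run the full sex-stratified composite-risk pipeline
#'
#' Orchestrates filter -> risk transform -> weight fitting -> repeated
#' train/test evaluation -> report, independently per sex.  The protocol
#' defaults match the composite-score analysis: 100 percentile bins, weight
#' grid step 0.025, 70 percent training fraction, 1000 repetitions.
#'
#' @param config a named list (or path to a JSON file) with fields:
#'   \describe{
#'     \item{cohort}{path to a tab-delimited cohort file, or a data.frame.}
#'     \item{measures}{named list of component vectors (as in
#'       [repeat_experiment()]) or character vector of
#'       `"name:comp1+comp2"` strings.}
#'     \item{n_bins, step, train_fraction, n_repetitions, seed}{protocol
#'       constants; defaults 100, 0.025, 0.7, 1000, 1.}
#'     \item{sexes}{subset of `c("female", "male")` to analyse.}
#'     \item{age_range}{inclusive bounds, default `c(40, 70)`.}
#'     \item{out_dir}{output directory (created if needed).}
#'   }
#' @return Invisibly, a list with per-sex [repeat_experiment()] results and
#'   the paths written: per sex and measure a per-percentile OR table
#'   `<sex>_<measure>_or.tsv` (`percentile`, `mean_or`, `sd_or`,
#'   `n_defined`), a `<sex>_summary.json` (fitted weights per repetition,
#'   AUC distributions, pairwise AUC comparison p-values) and a single
#'   `manifest.json` recording the resolved config, seed, package version
#'   and grid evaluations per repetition.  Outputs are deterministic:
#'   rerunning the same config yields byte-identical files.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- list(n_bins = 100L, step = 0.025, train_fraction = 0.7,
                   n_repetitions = 1000L, seed = 1L,
                   sexes = c("female", "male"), age_range = c(40L, 70L))
  for (f in names(defaults))
    if (is.null(config[[f]])) config[[f]] <- defaults[[f]]
  if (is.null(config$out_dir)) stop("config$out_dir is required", call. = FALSE)
  if (is.null(config$measures) || length(config$measures) == 0L)
    stop("at least one measure must be defined", call. = FALSE)
  measures <- parse_measures(config$measures)
  # unknown components must fail before any computation
  invisible(lapply(unlist(measures, use.names = FALSE), component_spec))

  cohort <- config$cohort
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  bad_sex <- setdiff(config$sexes, c("female", "male"))
  if (length(bad_sex))
    stop("unknown sex label(s): ", paste(bad_sex, collapse = ", "), call. = FALSE)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  paths <- character()
  for (sx in config$sexes) {
    sub <- cohort[cohort$sex == sx, , drop = FALSE]
    if (nrow(sub) < 1000L)
      warning("sex '", sx, "' has only ", nrow(sub), " individuals")
    sub <- apply_cohort_filters(sub, age_range = config$age_range)
    # fixed per-sex sub-seed (independent of which sexes are requested)
    sex_seed <- config$seed + match(sx, c("female", "male"))
    res <- repeat_experiment(sub, measures,
                             n_repetitions = config$n_repetitions,
                             train_fraction = config$train_fraction,
                             n_bins = config$n_bins, step = config$step,
                             seed = sex_seed)
    results[[sx]] <- res
    for (m in names(measures)) {
      tab <- data.frame(percentile = seq_len(config$n_bins) - 1L,
                        mean_or = res$measures[[m]]$or_mean,
                        sd_or = res$measures[[m]]$or_sd,
                        n_defined = res$measures[[m]]$n_defined)
      p <- file.path(config$out_dir, paste0(sx, "_", m, "_or.tsv"))
      write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
    pairs <- if (length(measures) > 1L) utils::combn(names(measures), 2L,
                                                     simplify = FALSE) else list()
    comparisons <- lapply(pairs, function(pr) {
      cmp <- compare_measures(res, pr[1], pr[2])
      list(measures = pr,
           auc_p_value = cmp$auc_test$p.value,
           auc_p_label = cmp$auc_test$p.label,
           auc_statistic = cmp$auc_test$statistic)
    })
    summary <- list(
      sex = sx,
      n_individuals = nrow(sub),
      n_cases = sum(sub$t2d),
      measures = lapply(names(measures), function(m) {
        mm <- res$measures[[m]]
        list(name = m, components = measures[[m]],
             weights_per_repetition = unname(apply(mm$weights, 1L, as.list)),
             mean_weights = as.list(colMeans(mm$weights)),
             test_auc = mm$auc,
             mean_test_auc = mean(mm$auc),
             mean_training_auc = mean(mm$training_auc))
      }),
      comparisons = comparisons)
    p <- file.path(config$out_dir, paste0(sx, "_summary.json"))
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, p)
  }

  manifest <- list(
    package = "crscore",
    version = as.character(packageVersion("crscore")),
    seed = config$seed,
    n_bins = config$n_bins, step = config$step,
    train_fraction = config$train_fraction,
    n_repetitions = config$n_repetitions,
    sexes = config$sexes, age_range = config$age_range,
    measures = measures,
    grid_evaluations_per_repetition = as.list(vapply(measures, function(comps) {
      nrow(enumerate_weights(length(comps), config$step))
    }, 0L)))
  p <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)
  invisible(list(results = results, paths = paths, manifest = manifest))
}

# "name:comp1+comp2" strings -> named list of component vectors.
parse_measures <- function(measures) {
  if (is.list(measures)) return(lapply(measures, as.character))
  out <- list()
  for (s in measures) {
    parts <- strsplit(s, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("measure definition must look like 'name:comp1+comp2': ", s,
           call. = FALSE)
    out[[parts[1]]] <- strsplit(parts[2], "+", fixed = TRUE)[[1]]
  }
  out
}
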