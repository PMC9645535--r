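#' Cross-validation fold bookkeeping
#'
#' Reproduces the k-fold split arithmetic used for pipeline training: `n`
#' cases are partitioned into `k` disjoint test sets of `test` cases each
#' (so every case is tested at most once), and each fold trains on the
#' remaining `train` cases. Only pre-augmentation originals are eligible as
#' test cases; augmented copies inherit their parent case's fold, so with a
#' 10:1 augmentation ratio a 50-case training split yields 550 training
#' sets per fold.
#'
#' @param n total cases.
#' @param train,test cases per fold for training and testing;
#'   `train + test` must not exceed `n` and `k * test` must not exceed `n`.
#' @param k number of folds.
#' @param seed seed for the shuffling.
#' @param ratio augmentation ratio used for the per-fold training-set count.
#' @return An object of class `fold_plan`: list of folds, each with
#'   `train_ids`, `test_ids` and `n_train_augmented`.
#' @export
evaluate_folds <- function(n = 75, train = 50, test = 25, k = 3, seed = 1L,
                           ratio = 10) {
  if (train + test > n)
    stop("evaluate_folds: train + test exceeds n", call. = FALSE)
  if (k * test > n)
    stop("evaluate_folds: k disjoint test sets of ", test,
         " do not fit in ", n, " cases", call. = FALSE)
  set.seed(seed)
  perm <- sample.int(n)
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    test_ids <- sort(perm[((f - 1) * test + 1):(f * test)])
    pool <- setdiff(perm, test_ids)
    train_ids <- sort(pool[seq_len(train)])
    folds[[f]] <- list(fold = f, train_ids = train_ids, test_ids = test_ids,
                       n_train_augmented = train * (ratio + 1))
  }
  structure(list(folds = folds, n = n, train = train, test = test, k = k,
                 ratio = ratio), class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d cases, %d folds of %d train / %d test\n",
              x$n, x$k, x$train, x$test))
  cat(sprintf("  augmented training sets per fold: %d (ratio %d:1)\n",
              x$folds[[1]]$n_train_augmented, x$ratio))
  invisible(x)
}

run_config_schema <- function() {
  list(
    paths = c("input", "output", "models"),
    preprocessing = c("iso_mm", "roi_factor", "window_low", "window_high"),
    augmentation = c("ratio", "n_points", "magnitude_mm", "sigma_mm"),
    models = c("roi", "thoracic", "abdominal", "roi_noncontrast",
               "abdominal_noncontrast"),
    folds = c("n_cases", "train", "test", "k"),
    seeds = c("cohort", "augment", "train", "folds"))
}

#' Read and validate a pipeline run configuration
#'
#' YAML configuration with sections `paths`, `preprocessing`,
#' `augmentation`, `models` (one [unet_config()] block per pipeline stage),
#' `folds` and `seeds`. Unknown keys are rejected with a message listing
#' them.
#'
#' @param path path to a YAML file.
#' @return The validated configuration list, class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("read_run_config: no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  schema <- run_config_schema()
  bad_top <- setdiff(names(cfg), names(schema))
  bad <- if (length(bad_top)) bad_top else character(0)
  for (sec in intersect(names(cfg), names(schema))) {
    if (sec == "models") next  # model blocks are unet_config arguments
    extra <- setdiff(names(cfg[[sec]]), schema[[sec]])
    if (length(extra)) bad <- c(bad, paste0(sec, ".", extra))
  }
  if ("models" %in% names(cfg)) {
    known_stages <- schema$models
    extra <- setdiff(names(cfg$models), known_stages)
    if (length(extra)) bad <- c(bad, paste0("models.", extra))
    known_args <- names(formals(unet_config))
    for (st in intersect(names(cfg$models), known_stages)) {
      extra <- setdiff(names(cfg$models[[st]]), known_args)
      if (length(extra)) bad <- c(bad, paste0("models.", st, ".", extra))
    }
  }
  if (length(bad))
    stop("read_run_config: unknown configuration keys: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Write a provenance record for an artifact directory
#'
#' Records the configuration (and its MD5 hash), the seeds in use, the
#' package version and a timestamp, as JSON, so every artifact directory is
#' traceable to the run that produced it.
#'
#' @param dir artifact directory (created if missing).
#' @param config configuration list used for the run.
#' @param seeds named list/vector of seeds.
#' @param stage free-text stage name.
#' @return Path of the provenance file, invisibly.
#' @export
write_provenance <- function(dir, config, seeds = list(), stage = "run") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile()
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  rec <- list(stage = stage,
              config = config,
              config_md5 = hash,
              seeds = seeds,
              package_version = as.character(utils::packageVersion("aortaseg")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "provenance.json")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
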