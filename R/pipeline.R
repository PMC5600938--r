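#' Build an experiment plan
#'
#' An experiment plan enumerates the grid of (task, level) cells and
#' architectures to run, at a configurable fraction of the reference study's
#' scale. The scale knob multiplies the dataset sizes (100,000 / 10,000 /
#' 10,000 train/validation/test images per condition) and the 100 training
#' epochs jointly, so a 10% plan trains on 10,000 images for 10 epochs.
#'
#' @param tasks a tibble with columns `task` (`"debris"` or `"clutter"`) and
#'   `level` (fragment count for debris: 10/30/50; digit count for clutter:
#'   3/4/5). Defaults to the full six-condition grid.
#' @param architectures character vector of [arch_spec()] preset names.
#' @param scale fraction of reference scale in `(0, 1]`.
#' @param seed base seed; every cell derives data, initialization and shuffle
#'   streams from it.
#' @param n_train,n_val,n_test,epochs explicit overrides of the scaled sizes.
#' @param time_average_loss passed to [training_config()]. Defaults to `TRUE`
#'   for plans below full scale (reduced-scale training needs the
#'   architecture-independent step size; see the vignette) and `FALSE` at
#'   `scale = 1`, the reference regime's literal summed objective.
#' @return An object of class `blt_plan`.
#' @examples
#' experiment_plan(architectures = c("B", "BLT"), scale = 0.01)
#' @export
experiment_plan <- function(tasks = NULL,
                            architectures = c("B", "B-F", "B-K", "BT", "BL", "BLT"),
                            scale = 0.1, seed = 1L,
                            n_train = NULL, n_val = NULL, n_test = NULL,
                            epochs = NULL, time_average_loss = scale < 1) {
  if (is.null(tasks)) {
    tasks <- tibble::tibble(
      task = rep(c("debris", "clutter"), each = 3),
      level = c(10, 30, 50, 3, 4, 5)
    )
  }
  stopifnot(scale > 0, scale <= 1)
  structure(
    list(
      tasks = tasks,
      architectures = architectures,
      scale = scale,
      seed = as.integer(seed),
      n_train = as.integer(n_train %||% max(1, round(1e5 * scale))),
      n_val = as.integer(n_val %||% max(1, round(1e4 * scale))),
      n_test = as.integer(n_test %||% max(1, round(1e4 * scale))),
      epochs = as.integer(epochs %||% max(1, round(100 * scale))),
      time_average_loss = isTRUE(time_average_loss)
    ),
    class = "blt_plan"
  )
}

#' @export
print.blt_plan <- function(x, ...) {
  cat(sprintf(
    "<blt_plan> %d condition(s) x %d architecture(s) at %.0f%% scale\n  %s train / %s val / %s test images, %d epochs, seed %d\n",
    nrow(x$tasks), length(x$architectures), 100 * x$scale,
    format(x$n_train, big.mark = ","), format(x$n_val, big.mark = ","),
    format(x$n_test, big.mark = ","), x$epochs, x$seed
  ))
  invisible(x)
}

# Config for one (task, level) cell of a plan.
cell_config <- function(plan, task, level, seed) {
  if (task == "debris") {
    stimulus_config(task = "debris", n_fragments = level, seed = seed)
  } else {
    stimulus_config(task = "clutter", n_digits = level, seed = seed)
  }
}

#' Run an experiment plan
#'
#' For every (task, level) cell: generates train/validation/test splits,
#' trains every architecture in the plan, evaluates on the test split, and
#' runs the full set of pairwise model comparisons (cluster-adjusted for
#' multi-digit tasks) with Benjamini-Hochberg FDR control within the cell.
#' Every stage draws from streams derived from the plan seed, so a rerun of
#' the same plan reproduces the same numbers. With `out_dir` set, each cell's
#' results are written as JSON as soon as they are computed and finished
#' cells are skipped on a rerun, making interrupted grids resumable; a cell
#' whose training fails is recorded as failed and the run continues.
#'
#' @param plan a [experiment_plan()].
#' @param out_dir optional directory for per-cell results and checkpoints.
#' @param verbose print progress.
#' @return An object of class `blt_experiment`: `results` (tibble with one
#'   row per cell x architecture: error rates), `tests` (tibble of pairwise
#'   comparisons), `models` (nested list of trained models), `plan`.
#' @export
run_experiment <- function(plan, out_dir = NULL, verbose = FALSE) {
  results <- list()
  tests <- list()
  models <- list()
  for (ci in seq_len(nrow(plan$tasks))) {
    task <- plan$tasks$task[ci]
    level <- plan$tasks$level[ci]
    cell_id <- paste0(task, level)
    cell_seed <- derive_seed(plan$seed, 1000L + ci)
    cfg <- cell_config(plan, task, level, cell_seed)
    if (verbose) message("cell ", cell_id, ": generating data")
    tr <- generate_dataset(cfg, plan$n_train, role = "train")
    va <- generate_dataset(cfg, plan$n_val, role = "val")
    te <- generate_dataset(cfg, plan$n_test, role = "test")
    evals <- list()
    n_targets <- if (task == "clutter") level else 1
    for (arch in plan$architectures) {
      cache <- if (!is.null(out_dir)) {
        file.path(out_dir, sprintf("cell_%s_%s.json", cell_id, arch))
      }
      if (!is.null(cache) && file.exists(cache)) {
        if (verbose) message("  ", arch, ": cached, skipping")
        cached <- jsonlite::read_json(cache, simplifyVector = TRUE)
        results[[length(results) + 1]] <- tibble::as_tibble(cached$result)
        next
      }
      if (verbose) message("  training ", arch)
      spec <- arch_spec(arch)
      tc <- training_config(epochs = plan$epochs,
                            seed = derive_seed(cell_seed, match(arch, plan$architectures)),
                            time_average_loss = plan$time_average_loss)
      ev <- NULL
      row <- tryCatch({
        fit <- train(spec, tr, va, config = tc, verbose = verbose)
        ev <- evaluate(fit, te)
        models[[cell_id]][[arch]] <- fit
        tibble::tibble(
          task = task, level = level, architecture = arch,
          error_rate = ev$error_rate, n_test = ev$n,
          final_val_err = utils::tail(fit$log$val_err, 1),
          status = "ok"
        )
      }, error = function(e) {
        tibble::tibble(
          task = task, level = level, architecture = arch,
          error_rate = NA_real_, n_test = plan$n_test,
          final_val_err = NA_real_, status = paste("failed:", conditionMessage(e))
        )
      })
      if (!is.null(ev)) evals[[arch]] <- ev
      results[[length(results) + 1]] <- row
      if (!is.null(cache)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        jsonlite::write_json(list(result = row), cache, auto_unbox = TRUE,
                             digits = NA)
      }
    }
    if (length(evals) >= 2) {
      cell_tests <- pairwise_model_tests(evals, per_digit = (task == "clutter"))
      cell_tests$task <- task
      cell_tests$level <- level
      tests[[length(tests) + 1]] <- cell_tests
    }
  }
  structure(
    list(
      results = dplyr::bind_rows(results),
      tests = if (length(tests)) dplyr::bind_rows(tests) else tibble::tibble(),
      models = models,
      plan = plan
    ),
    class = "blt_experiment"
  )
}

#' @export
print.blt_experiment <- function(x, ...) {
  cat("<blt_experiment>\n")
  print(results_table(x))
  invisible(x)
}

#' Evaluate a trained model on a different stimulus condition
#'
#' Applies a trained model, with its own training-condition normalization
#' statistics and no retraining, to a test split from another condition —
#' e.g. a model trained under heavy debris tested on unoccluded digits.
#'
#' @param model a trained `blt_model`.
#' @param test_split a `blt_dataset` at the model's input resolution.
#' @return A `blt_eval`.
#' @export
cross_condition_eval <- function(model, test_split) {
  if (dim(test_split$images)[1] != model$spec$input_side) {
    stop("test split resolution does not match the model input.")
  }
  evaluate(model, test_split)
}

#' Error-rate table of an experiment
#'
#' Pivots an experiment's results into the conventional layout: one row per
#' (task, level), one column per architecture, entries in percent.
#'
#' @param experiment a `blt_experiment`.
#' @return A tibble.
#' @export
results_table <- function(experiment) {
  experiment$results |>
    dplyr::mutate(error_pct = round(100 * .data$error_rate, 2)) |>
    dplyr::select("task", "level", "architecture", "error_pct") |>
    tidyr::pivot_wider(names_from = "architecture", values_from = "error_pct")
}

#' Significance matrix of an experiment cell
#'
#' Boolean matrix of FDR-controlled pairwise differences between
#' architectures within one (task, level) image set.
#'
#' @param experiment a `blt_experiment`.
#' @param task,level the cell.
#' @return A logical matrix (architectures x architectures).
#' @export
significance_matrix <- function(experiment, task, level) {
  tt <- dplyr::filter(experiment$tests,
                      .data$task == !!task, .data$level == !!level)
  archs <- union(tt$model_a, tt$model_b)
  m <- matrix(FALSE, length(archs), length(archs),
              dimnames = list(archs, archs))
  for (i in seq_len(nrow(tt))) {
    m[tt$model_a[i], tt$model_b[i]] <- tt$significant[i]
    m[tt$model_b[i], tt$model_a[i]] <- tt$significant[i]
  }
  m
}
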