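# Taguchi experimental design for SOM hyperparameters: run scheduling,
# partial-F stepwise term selection, OLS response modelling, and derivation
# of the optimal SOM configuration.

#' Built-in Taguchi design plan
#'
#' The 36-run robust design over the nine SOM hyperparameters, run with 3
#' replicas per combination. Categorical levels are stored lowercase.
#'
#' @return object of class `design_plan`: list with `runs` (36-row
#'   data.frame) and `replicas`.
#' @export
builtin_taguchi_plan <- function() {
  txt <- "
100 hexagonal   sheet    batch      gaussian inverse 2 1000 0.01
225 hexagonal   cylinder batch      bubble   power   3 3000 0.05
400 hexagonal   toroid   batch      ep       linear  1 5000 0.09
100 hexagonal   sheet    sequential gaussian linear  3 1000 0.09
225 hexagonal   cylinder sequential bubble   inverse 1 3000 0.01
400 hexagonal   toroid   sequential ep       power   2 5000 0.05
100 rectangular cylinder sequential gaussian linear  1 5000 0.05
225 rectangular toroid   sequential bubble   inverse 2 1000 0.09
400 rectangular sheet    sequential ep       power   3 3000 0.01
100 rectangular toroid   batch      gaussian power   1 3000 0.01
225 rectangular sheet    batch      bubble   linear  2 5000 0.05
400 rectangular cylinder batch      ep       inverse 3 1000 0.09
100 hexagonal   toroid   sequential bubble   power   1 1000 0.05
225 hexagonal   sheet    sequential ep       linear  2 3000 0.09
400 hexagonal   cylinder sequential gaussian inverse 3 5000 0.01
100 rectangular toroid   sequential bubble   inverse 3 3000 0.09
225 rectangular sheet    sequential ep       power   1 5000 0.01
400 rectangular cylinder sequential gaussian linear  2 1000 0.05
100 rectangular sheet    sequential bubble   linear  3 5000 0.01
225 rectangular cylinder sequential ep       inverse 1 1000 0.05
400 rectangular toroid   sequential gaussian power   2 3000 0.09
100 rectangular cylinder batch      bubble   power   2 5000 0.09
225 rectangular toroid   batch      ep       linear  3 1000 0.01
400 rectangular sheet    batch      gaussian inverse 1 3000 0.05
100 hexagonal   cylinder batch      ep       power   2 1000 0.01
225 hexagonal   toroid   batch      gaussian linear  3 3000 0.05
400 hexagonal   sheet    batch      bubble   inverse 1 5000 0.09
100 hexagonal   cylinder batch      ep       linear  1 3000 0.09
225 hexagonal   toroid   batch      gaussian inverse 2 5000 0.01
400 hexagonal   sheet    batch      bubble   power   3 1000 0.05
100 hexagonal   toroid   sequential ep       inverse 3 5000 0.05
225 hexagonal   sheet    sequential gaussian power   1 1000 0.09
400 hexagonal   cylinder sequential bubble   linear  2 3000 0.01
100 rectangular sheet    batch      ep       inverse 2 3000 0.05
225 rectangular cylinder batch      gaussian power   3 5000 0.09
400 rectangular toroid   batch      bubble   linear  1 1000 0.01"
  runs <- utils::read.table(text = txt, col.names = c(
    "map_size", "lattice", "shape", "algorithm", "neighbour", "alpha_type",
    "radius", "training_length", "alpha0"), stringsAsFactors = FALSE)
  stopifnot(nrow(runs) == 36,
            all(runs$lattice %in% SOM_LATTICES),
            all(runs$shape %in% SOM_SHAPES),
            all(runs$algorithm %in% SOM_ALGORITHMS),
            all(runs$neighbour %in% SOM_NEIGHBOURS),
            all(runs$alpha_type %in% SOM_ALPHA_TYPES))
  structure(list(runs = runs, replicas = 3L), class = "design_plan")
}

#' Schedule the experiments of a design plan
#'
#' Enumerates (run, replica, case) combinations; `runs x replicas x cases`
#' records (432 for the built-in plan with 4 data-set cases).
#'
#' @param plan a `design_plan`.
#' @param cases character vector of data-set case names.
#' @param replicas overrides `plan$replicas`.
#' @param runs run indices to include (default all).
#' @return data.frame with columns `run`, `replica`, `case`.
#' @export
design_schedule <- function(plan, cases, replicas = plan$replicas,
                            runs = seq_len(nrow(plan$runs))) {
  expand.grid(run = runs, replica = seq_len(replicas), case = cases,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Execute a design plan
#'
#' Trains one SOM per (run, replica, case) with deterministically derived
#' sub-seeds and scores it with the clustering-efficiency index after
#' complete-linkage clustering of the prototypes with Mojena's rule
#' (`z = 2.75`; if the rule returns a single cluster, a 2-cluster cut is
#' used so the index is defined). Training failures are recorded as missing
#' responses, not raised.
#'
#' @param plan a `design_plan` (e.g. [builtin_taguchi_plan()]).
#' @param datasets named list of descriptor matrices or ensembles (already
#'   ED-filtered); names are the case labels.
#' @param seed master seed.
#' @param replicas,runs optional reductions of the plan (smoke runs).
#' @param z Mojena constant used for the response clustering.
#' @return object of class `design_result` with `records` (one row per
#'   experiment: run, replica, case, response, k, elapsed) and the plan.
#' @export
run_design <- function(plan, datasets, seed = 1, replicas = plan$replicas,
                       runs = seq_len(nrow(plan$runs)), z = 2.75) {
  stopifnot(length(datasets) >= 1, !is.null(names(datasets)))
  sched <- design_schedule(plan, names(datasets), replicas, runs)
  recs <- vector("list", nrow(sched))
  for (r in seq_len(nrow(sched))) {
    run_i <- sched$run[r]; rep_i <- sched$replica[r]; case_i <- sched$case[r]
    row <- plan$runs[run_i, ]
    sub_seed <- derive_seed(seed, sprintf("design-%d-%d-%s", run_i, rep_i, case_i))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      cfg <- som_config(map_size = row$map_size, lattice = row$lattice,
                        shape = row$shape, algorithm = row$algorithm,
                        neighbour = row$neighbour, alpha_type = row$alpha_type,
                        radius = row$radius, training_length = row$training_length,
                        alpha0 = row$alpha0, seed = sub_seed, warn_size = FALSE)
      X <- as_descriptor_matrix(datasets[[case_i]])
      som <- som_train(som_init(cfg, X), X)
      tree <- linkage_prototypes(som, "complete")
      k <- max(mojena_k(tree, z), 2L)
      memb <- stats::cutree(tree$hclust, k = k)
      c(performance_index(som, memb), k)
    }, error = function(e) c(NA_real_, NA_real_))
    recs[[r]] <- data.frame(run = run_i, replica = rep_i, case = case_i,
                            response = res[1], k = res[2],
                            elapsed = proc.time()[["elapsed"]] - t0)
  }
  records <- cbind(do.call(rbind, recs),
                   plan$runs[sched$run, , drop = FALSE], row.names = NULL)
  structure(list(records = records, plan = plan, z = z, seed = seed),
            class = "design_result")
}

design_candidates <- function(records) {
  cand <- c("map_size", "lattice", "shape", "algorithm", "neighbour",
            "alpha_type", "radius", "training_length", "alpha0")
  cand <- cand[cand %in% names(records)]
  if ("case" %in% names(records) && length(unique(records$case)) >= 2)
    cand <- c(cand, "case")
  keep <- vapply(cand, function(v) length(unique(records[[v]])) >= 2, logical(1))
  cand[keep]
}

prepare_design_frame <- function(records, candidates) {
  df <- records[!is.na(records$response), , drop = FALSE]
  for (v in candidates)
    if (!is.numeric(df[[v]])) df[[v]] <- factor(df[[v]])
  df
}

#' Stepwise selection of significant SOM parameters
#'
#' Mixed forward/backward stepwise selection on main effects with partial
#' F-tests at `p_enter = p_leave = 0.05`. Numeric parameters enter linearly;
#' categorical parameters enter or leave as whole dummy blocks. The data-set
#' case (the molecule-type variable) is a candidate whenever two or more
#' cases are present. Deterministic given the records.
#'
#' @param records `design_result` records data.frame (or a `design_result`).
#' @param p_enter,p_leave F-test thresholds.
#' @param candidates candidate term names; defaults to every varying SOM
#'   parameter (plus `case`).
#' @return character vector of selected terms (possibly empty).
#' @export
stepwise_select <- function(records, p_enter = 0.05, p_leave = 0.05,
                            candidates = NULL) {
  if (inherits(records, "design_result")) records <- records$records
  candidates <- candidates %||% design_candidates(records)
  df <- prepare_design_frame(records, candidates)
  if (nrow(df) < 3 || stats::sd(df$response) == 0) return(character(0))
  selected <- character(0)
  repeat {
    changed <- FALSE
    fit <- stats::lm(stats::reformulate(c("1", selected), "response"), data = df)
    remaining <- setdiff(candidates, selected)
    if (length(remaining)) {
      a1 <- stats::add1(fit, scope = stats::reformulate(c(selected, remaining)),
                        test = "F")
      pv <- a1[["Pr(>F)"]][-1]
      names(pv) <- rownames(a1)[-1]
      pv <- pv[!is.na(pv)]
      if (length(pv) && min(pv) <= p_enter) {
        selected <- c(selected, names(pv)[which.min(pv)])
        changed <- TRUE
        fit <- stats::lm(stats::reformulate(c("1", selected), "response"), data = df)
      }
    }
    if (length(selected)) {
      d1 <- stats::drop1(fit, test = "F")
      pv <- d1[["Pr(>F)"]][-1]
      names(pv) <- rownames(d1)[-1]
      pv <- pv[!is.na(pv)]
      if (length(pv) && max(pv) > p_leave) {
        selected <- setdiff(selected, names(pv)[which.max(pv)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  selected
}

#' Fit the linear response model on selected terms
#'
#' Ordinary least squares of the clustering-efficiency response on the
#' selected main effects, with the fit summary (`R2`, adjusted `R2`, RMSE)
#' and a per-term effect table (Nparm, DF, sum of squares, F ratio, p).
#' Aliased (collinear) columns are dropped with a warning.
#'
#' @param records `design_result` records (or a `design_result`).
#' @param terms selected term names, e.g. from [stepwise_select()].
#' @return object of class `response_model`: list with `fit`, `terms`, `r2`,
#'   `r2_adj`, `rmse`, `effects`, `mean_response`.
#' @export
fit_response_model <- function(records, terms) {
  if (inherits(records, "design_result")) records <- records$records
  df <- prepare_design_frame(records, terms)
  fit <- stats::lm(stats::reformulate(c("1", terms), "response"), data = df)
  if (any(is.na(stats::coef(fit))))
    warnf("aliased terms dropped from the response model")
  sm <- summary(fit)
  effects <- NULL
  if (length(terms)) {
    d1 <- stats::drop1(fit, test = "F")
    asg <- attr(stats::model.matrix(fit), "assign")
    nparm <- vapply(seq_along(terms), function(i)
      sum(asg == i & !is.na(stats::coef(fit))), integer(1))
    effects <- data.frame(term = rownames(d1)[-1],
                          nparm = nparm,
                          df = d1$Df[-1],
                          sum_sq = d1[["Sum of Sq"]][-1],
                          f_ratio = d1[["F value"]][-1],
                          p_value = d1[["Pr(>F)"]][-1])
  }
  structure(list(fit = fit, terms = terms, r2 = sm$r.squared,
                 r2_adj = sm$adj.r.squared, rmse = sm$sigma,
                 effects = effects, mean_response = mean(df$response)),
            class = "response_model")
}

#' @export
print.response_model <- function(x, ...) {
  cat(sprintf("Response model: R2 = %.3f, R2_adj = %.3f, RMSE = %.3g\n",
              x$r2, x$r2_adj, x$rmse))
  if (!is.null(x$effects)) print(x$effects, row.names = FALSE)
  invisible(x)
}

# Candidate levels of each parameter on the design grid.
design_grid_levels <- function() {
  list(map_size = c(100, 225, 400), lattice = SOM_LATTICES, shape = SOM_SHAPES,
       algorithm = SOM_ALGORITHMS, neighbour = SOM_NEIGHBOURS,
       alpha_type = SOM_ALPHA_TYPES, radius = c(1, 2, 3),
       training_length = c(1000, 3000, 5000), alpha0 = c(0.01, 0.05, 0.09))
}

default_parameter_values <- function() {
  list(map_size = 100, lattice = "hexagonal", shape = "sheet",
       algorithm = "batch", neighbour = "gaussian", alpha_type = "inverse",
       radius = 3, training_length = 5000, alpha0 = 0.05)
}

#' Optimal SOM parameters from a fitted response model
#'
#' Minimizes the predicted response over the tested grid of the significant
#' parameters; parameters not in the model are fixed at the package
#' defaults.
#'
#' @param model a [fit_response_model()] result.
#' @param case data-set case to predict for, when `case` is in the model.
#' @param seed seed stored in the returned configuration.
#' @return list with `config` (a [som_config()]), `predicted` (response at
#'   the optimum) and `grid_row` (the optimal parameter values).
#' @export
optimal_parameters <- function(model, case = NULL, seed = 1) {
  lv <- design_grid_levels()
  defaults <- default_parameter_values()
  sig <- intersect(model$terms, names(lv))
  fixed <- defaults[setdiff(names(lv), sig)]
  grid_args <- lv[sig]
  if ("case" %in% model$terms) {
    case_levels <- levels(model$fit$model$case)
    grid_args$case <- case %||% case_levels
  }
  grid <- if (length(grid_args))
    expand.grid(grid_args, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  else data.frame(row.names = 1)
  newdata <- grid
  for (nm in names(fixed)) newdata[[nm]] <- fixed[[nm]]
  pred <- stats::predict(model$fit, newdata = newdata)
  best <- which.min(pred)
  opt <- as.list(newdata[best, setdiff(names(newdata), "case"), drop = FALSE])
  cfg <- do.call(som_config, c(opt, list(seed = seed, warn_size = FALSE)))
  list(config = cfg, predicted = unname(pred[best]),
       grid_row = newdata[best, , drop = FALSE])
}

#' Validate the model optimum by retraining
#'
#' Trains a SOM at the optimal configuration on each data set and reports
#' the actual clustering-efficiency response next to the model prediction.
#'
#' @param model a [fit_response_model()] result.
#' @param datasets named list of descriptor matrices / ensembles.
#' @param seed master seed.
#' @param z Mojena constant for the response clustering.
#' @return data.frame with one row per case: predicted and actual response.
#' @export
validate_optimum <- function(model, datasets, seed = 1, z = 2.75) {
  rows <- lapply(names(datasets), function(case_i) {
    has_case <- "case" %in% model$terms
    opt <- optimal_parameters(model, case = if (has_case) case_i else NULL,
                              seed = derive_seed(seed, paste0("validate-", case_i)))
    X <- as_descriptor_matrix(datasets[[case_i]])
    som <- som_train(som_init(opt$config, X), X)
    tree <- linkage_prototypes(som, "complete")
    k <- max(mojena_k(tree, z), 2L)
    actual <- performance_index(som, stats::cutree(tree$hclust, k = k))
    data.frame(case = case_i, predicted = opt$predicted, actual = actual,
               map_size = opt$config$map_size, radius = opt$config$radius,
               training_length = opt$config$training_length,
               neighbour = opt$config$neighbour)
  })
  do.call(rbind, rows)
}
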