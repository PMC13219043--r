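#' Registration methods available in the trial protocol
#' @return Character vector of method names.
#' @export
registration_methods <- function() c("coarse_only", "p2pt", "p2pl", "sparse_p2pl")

# Run one fine-registration method from a shared coarse initialization.
run_method <- function(method, probe, index, coarse_transform, params) {
  switch(method,
    coarse_only = list(transform = coarse_transform, termination = "closed_form",
                       n_iter = 0L),
    p2pt = {
      r <- icp_point_to_point(probe, index, coarse_transform, params)
      list(transform = r$transform, termination = r$termination,
           n_iter = nrow(r$trace))
    },
    p2pl = {
      r <- icp_point_to_plane(probe, index, coarse_transform, params)
      list(transform = r$transform, termination = r$termination,
           n_iter = nrow(r$trace))
    },
    sparse_p2pl = {
      r <- sparse_icp_register(probe, index, coarse_transform, params)
      list(transform = r$transform, termination = r$termination,
           n_iter = nrow(r$trace))
    },
    stop(sprintf("unknown method '%s'", method), call. = FALSE))
}

#' Repeated paired registration trials
#'
#' The validation protocol: for each repeat a fresh phantom is generated
#' (seed = `base_seed + repeat - 1`), one coarse solution is fitted from its
#' noisy landmarks, and every method runs from that identical initialization
#' on the identical probe points — so per-repeat differences between methods
#' reflect the fine-registration algorithms alone. Per-repeat inputs are
#' checksummed and the checksum stored with every method record, making the
#' identical-inputs guarantee auditable. Method failures are recorded per
#' repeat (never silently dropped) and excluded pairwise from summaries.
#'
#' @param config a [phantom_config()] describing the study conditions.
#' @param methods character vector from [registration_methods()]; the first
#'   entry is the reference for paired differences unless `reference` says
#'   otherwise.
#' @param n_repeats number of repeats (default 30, the trial protocol).
#' @param base_seed integer; repeat `i` uses phantom seed `base_seed + i - 1`.
#' @param params a [sparse_icp_params()] shared by all fine methods.
#' @param k_neighbors neighbourhood size for target normal estimation.
#' @param reference method name for paired differences.
#' @return A `trial_summary`: `per_repeat` data frame (one row per repeat x
#'   method with all four metrics), `summary` (mean and SD per method),
#'   `paired` (per-repeat metric differences vs the reference), `failures`
#'   count per method, `seeds`, and the `config` snapshot.
#' @export
run_trials <- function(config = phantom_config(), methods = "sparse_p2pl",
                       n_repeats = 30L, base_seed = 1L,
                       params = sparse_icp_params(), k_neighbors = 30L,
                       reference = methods[1]) {
  stopifnot(length(methods) >= 1L, all(methods %in% registration_methods()),
            n_repeats >= 1L, reference %in% methods)
  validate_phantom_config(config)
  rows <- list()
  seeds <- as.integer(base_seed) + seq_len(n_repeats) - 1L
  for (i in seq_len(n_repeats)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[i])
    phantom <- make_phantom(cfg)
    target <- estimate_normals(phantom$target_cloud, k_neighbors)
    index <- build_spatial_index(target)
    coarse <- kabsch_align(phantom$coarse_landmarks$source,
                           phantom$coarse_landmarks$target)
    checksum <- input_checksum(phantom)
    for (m in methods) {
      res <- tryCatch(run_method(m, phantom$probe_points, index,
                                 coarse$transform, params),
                      error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          repeat_id = i, seed = seeds[i], method = m, failed = TRUE,
          error = conditionMessage(res), tre = NA_real_, rmse = NA_real_,
          std = NA_real_, max_err = NA_real_, termination = NA_character_,
          n_iter = NA_integer_, checksum = checksum)
      } else {
        met <- evaluate_registration(phantom, res$transform)
        rows[[length(rows) + 1L]] <- data.frame(
          repeat_id = i, seed = seeds[i], method = m, failed = FALSE,
          error = "", tre = met$tre, rmse = met$rmse, std = met$std,
          max_err = met$max_err, termination = res$termination,
          n_iter = res$n_iter, checksum = checksum)
      }
    }
  }
  per_repeat <- do.call(rbind, rows)
  rownames(per_repeat) <- NULL
  structure(list(
    per_repeat = per_repeat,
    summary = summarize_trials(per_repeat, methods),
    paired = paired_differences(per_repeat, methods, reference),
    failures = vapply(methods, function(m) {
      sum(per_repeat$failed[per_repeat$method == m])
    }, integer(1)),
    reference = reference,
    seeds = seeds,
    config = config
  ), class = "trial_summary")
}

input_checksum <- function(phantom) {
  v <- c(phantom$probe_points$points, phantom$coarse_landmarks$source,
         phantom$coarse_landmarks$target)
  sprintf("%.0f", sum(abs(v)) * 1e6 %% 1e15)
}

summarize_trials <- function(per_repeat, methods) {
  metrics <- c("tre", "rmse", "std", "max_err")
  out <- do.call(rbind, lapply(methods, function(m) {
    d <- per_repeat[per_repeat$method == m & !per_repeat$failed, , drop = FALSE]
    row <- data.frame(method = m, n = nrow(d))
    for (met in metrics) {
      row[[paste0(met, "_mean")]] <- if (nrow(d)) mean(d[[met]]) else NA_real_
      row[[paste0(met, "_sd")]] <- if (nrow(d) > 1) stats::sd(d[[met]]) else NA_real_
    }
    row
  }))
  rownames(out) <- NULL
  out
}

# per-repeat differences method - reference, complete (both succeeded) pairs
paired_differences <- function(per_repeat, methods, reference) {
  metrics <- c("tre", "rmse", "std", "max_err")
  ref <- per_repeat[per_repeat$method == reference & !per_repeat$failed, ]
  out <- list()
  for (m in setdiff(methods, reference)) {
    d <- per_repeat[per_repeat$method == m & !per_repeat$failed, ]
    common <- intersect(ref$repeat_id, d$repeat_id)
    if (length(common) == 0L) next
    di <- data.frame(method = m, repeat_id = common)
    for (met in metrics) {
      di[[paste0("d_", met)]] <- d[[met]][match(common, d$repeat_id)] -
        ref[[met]][match(common, ref$repeat_id)]
    }
    out[[m]] <- di
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf("<trial_summary> %d repeats on '%s' phantoms (base seed %d)\n",
              length(x$seeds), x$config$shape, x$seeds[1]))
  s <- x$summary
  cat(sprintf("%-12s %14s %14s %14s %14s\n", "method", "TRE (mm)", "RMSE (mm)",
              "STD (mm)", "MaxErr (mm)"))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("%-12s %6.3f +/- %5.3f %6.3f +/- %5.3f %6.3f +/- %5.3f %6.3f +/- %5.3f\n",
                s$method[i], s$tre_mean[i], s$tre_sd[i], s$rmse_mean[i],
                s$rmse_sd[i], s$std_mean[i], s$std_sd[i], s$max_err_mean[i],
                s$max_err_sd[i]))
  }
  if (any(x$failures > 0)) {
    cat("failures:", paste(sprintf("%s=%d", names(x$failures), x$failures),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Four-configuration ablation
#'
#' Evaluates, under the identical-inputs protocol of [run_trials()], the four
#' registration configurations: coarse only; coarse + point-to-point ICP;
#' coarse + point-to-plane (no sparse weighting); coarse + sparse
#' point-to-plane (the full method). Paired differences are taken against the
#' full method.
#'
#' @inheritParams run_trials
#' @return A `trial_summary` over the four configurations.
#' @export
run_ablation <- function(config = phantom_config(), n_repeats = 30L,
                         base_seed = 1L, params = sparse_icp_params(),
                         k_neighbors = 30L) {
  run_trials(config,
             methods = c("coarse_only", "p2pt", "p2pl", "sparse_p2pl"),
             n_repeats = n_repeats, base_seed = base_seed, params = params,
             k_neighbors = k_neighbors, reference = "sparse_p2pl")
}

#' Sampling-count sweep
#'
#' Repeats the full pipeline (coarse + sparse point-to-plane) at each probe
#' count and reports mean and SD of the TRE per count, tracing how accuracy
#' improves (then plateaus) with more intraoperative samples.
#'
#' @inheritParams run_trials
#' @param counts integer vector of probe counts (each >= 3).
#' @return A `sample_sweep` list: `counts`, `summary` data frame
#'   (count, n, tre_mean, tre_sd), and the per-count `trial_summary` objects.
#' @export
run_sample_sweep <- function(config = phantom_config(), counts = c(10L, 30L),
                             n_repeats = 30L, base_seed = 1L,
                             params = sparse_icp_params(), k_neighbors = 30L) {
  stopifnot(all(counts >= 3L))
  trials <- lapply(counts, function(cn) {
    cfg <- config
    cfg$n_probe <- as.integer(cn)
    validate_phantom_config(cfg)
    run_trials(cfg, methods = "sparse_p2pl", n_repeats = n_repeats,
               base_seed = base_seed, params = params,
               k_neighbors = k_neighbors)
  })
  summary <- do.call(rbind, lapply(seq_along(counts), function(i) {
    s <- trials[[i]]$summary
    data.frame(n_probe = counts[i], n = s$n, tre_mean = s$tre_mean,
               tre_sd = s$tre_sd)
  }))
  structure(list(counts = counts, summary = summary, trials = trials),
            class = "sample_sweep")
}

#' @export
print.sample_sweep <- function(x, ...) {
  cat("<sample_sweep> mean TRE by probe count:\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  n_probe %3d: TRE %.3f +/- %.3f mm (n = %d)\n",
                x$summary$n_probe[i], x$summary$tre_mean[i],
                x$summary$tre_sd[i], x$summary$n[i]))
  }
  invisible(x)
}
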