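#' Restoration plan
#'
#' Stage toggles and parameter blocks for [run_restoration()]. Stages run
#' in the fixed order charge -> destripe -> align -> deconvolve -> detect ->
#' inpaint -> validate; geometric and intensity corrections precede PSF
#' estimation, and slice replacement comes last so only slices that remain
#' unrecoverable after correction are rebuilt.
#'
#' @param charge `list(enabled, radius)` rolling-ball charge correction.
#' @param destripe `list(enabled, spec)` with a [stripe_filter_spec()].
#' @param align `list(enabled, levels)` multi-scale drift correction.
#' @param deconvolve `list(enabled, params, sigma)` with
#'   [deconvolution_params()]; `sigma = "auto"` estimates a PSF per slice.
#' @param detect `list(enabled, log_sigma, rule, k, cutoff)` sharpness-based
#'   artifactual-slice detection.
#' @param inpaint `list(enabled, params)` with [inpaint_params()]; replaces
#'   every flagged slice.
#' @param validate `list(enabled, plane_range)` FRC acceptance of replaced
#'   slices (default reference distance 3 planes).
#' @param n_workers Workers for per-slice stages.
#' @param seed Seed echoed into the report (the pipeline itself is
#'   deterministic).
#' @return A `RestorationPlan` list.
#' @export
restoration_plan <- function(charge = list(enabled = FALSE, radius = 25),
                             destripe = list(enabled = FALSE, spec = stripe_filter_spec()),
                             align = list(enabled = FALSE, levels = 3L),
                             deconvolve = list(enabled = FALSE,
                                               params = deconvolution_params(),
                                               sigma = "auto"),
                             detect = list(enabled = TRUE, log_sigma = 2,
                                           rule = "robust_z", k = 3, cutoff = NULL),
                             inpaint = list(enabled = FALSE,
                                            params = inpaint_params("dct")),
                             validate = list(enabled = TRUE, plane_range = 3),
                             n_workers = 1L, seed = 1L) {
  if (!is.null(align$levels)) align$levels <- as.integer(align$levels)
  if (!is.null(validate$plane_range)) {
    validate$plane_range <- as.integer(validate$plane_range)
  }
  plan <- structure(list(charge = charge, destripe = destripe, align = align,
                         deconvolve = deconvolve, detect = detect,
                         inpaint = inpaint, validate = validate,
                         n_workers = as.integer(n_workers), seed = seed),
                    class = "RestorationPlan")
  # validate alone is a no-op, so it does not count as an enabled stage
  enabled <- vapply(plan[1:6], function(st) isTRUE(st$enabled), logical(1))
  if (!any(enabled)) stop("at least one pipeline stage must be enabled")
  if (isTRUE(validate$enabled) && validate$plane_range < 1) {
    stop("`validate$plane_range` must be >= 1")
  }
  plan
}

#' Run the full restoration workflow
#'
#' Applies the enabled stages of `plan` in the fixed order charge ->
#' destripe -> align -> deconvolve -> detect -> inpaint -> validate. Flagged
#' slices that survive correction are removed and rebuilt by structural
#' inpainting from their neighbours, and each replaced slice is accepted
#' when its global FRC score against a reference slice `plane_range` planes
#' away does not decrease. Deterministic given `stack` and `plan`; a stage
#' failure aborts with the stage name.
#'
#' @param stack An [image_stack()].
#' @param plan A [restoration_plan()].
#' @return List with `restored` (an [image_stack()]) and `report`, a
#'   `RestorationReport`: per-stage status, quality reports before/after,
#'   per-replaced-slice FRC validation, replaced slice indices, and the
#'   plan echo.
#' @export
run_restoration <- function(stack, plan = restoration_plan()) {
  if (isTRUE(plan$inpaint$enabled) && isTRUE(plan$validate$enabled) &&
      n_slices(stack) < 2 * plan$validate$plane_range + 1) {
    stop("stack too short for FRC validation at plane_range ",
         plan$validate$plane_range)
  }
  cur <- stack
  status <- list()
  stage <- function(name, enabled, fun) {
    if (!isTRUE(enabled)) {
      status[[name]] <<- "skipped"
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    status[[name]] <<- "done"
    res
  }

  stage("charge", plan$charge$enabled, function() {
    cur <<- map_slices(cur, function(img) rolling_ball(img, plan$charge$radius)$corrected,
                       plan$n_workers)
  })
  stage("destripe", plan$destripe$enabled, function() {
    cur <<- map_slices(cur, function(img) remove_stripes(img, plan$destripe$spec),
                       plan$n_workers)
  })
  stage("align", plan$align$enabled, function() {
    cur <<- align_stack(cur, plan$align$levels)$aligned
  })
  sigmas <- NULL
  stage("deconvolve", plan$deconvolve$enabled, function() {
    res <- deconvolve_stack(cur, plan$deconvolve$params,
                            sigma = plan$deconvolve$sigma,
                            n_workers = plan$n_workers)
    sigmas <<- res$sigmas
    cur <<- res$stack
  })
  quality_before <- NULL
  flagged <- integer(0)
  stage("detect", plan$detect$enabled, function() {
    quality_before <<- detect_artifactual_slices(
      cur, log_sigma = plan$detect$log_sigma, rule = plan$detect$rule,
      k = plan$detect$k, cutoff = plan$detect$cutoff)
    flagged <<- quality_before$flagged
  })
  pre_inpaint <- cur
  replaced <- integer(0)
  stage("inpaint", plan$inpaint$enabled, function() {
    if (length(flagged)) {
      mask <- mask_from_slices(dim(cur$data), flagged)
      cur <<- inpaint(cur, mask, plan$inpaint$params)
      replaced <<- flagged
    }
  })
  validation <- NULL
  stage("validate", plan$validate$enabled, function() {
    if (length(replaced)) {
      validation <<- frc_validation(pre_inpaint, cur, replaced,
                                    plane_range = plan$validate$plane_range,
                                    flagged = flagged)
    }
  })
  quality_after <- if (isTRUE(plan$detect$enabled)) {
    detect_artifactual_slices(cur, log_sigma = plan$detect$log_sigma,
                              rule = plan$detect$rule, k = plan$detect$k,
                              cutoff = plan$detect$cutoff)
  } else NULL

  report <- structure(
    list(stages = status, quality_before = quality_before,
         quality_after = quality_after, frc_validation = validation,
         replaced_slices = replaced, psf_sigmas = sigmas, plan = plan),
    class = "RestorationReport"
  )
  list(restored = cur, report = report)
}

#' @export
print.RestorationReport <- function(x, ...) {
  done <- names(x$stages)[unlist(x$stages) == "done"]
  cat("RestorationReport\n  stages run:", paste(done, collapse = ", "), "\n")
  cat("  replaced slices:",
      if (length(x$replaced_slices)) paste(x$replaced_slices, collapse = ", ") else "none",
      "\n")
  if (!is.null(x$frc_validation) && nrow(x$frc_validation)) {
    cat(sprintf("  FRC validation: %d/%d accepted (mean before %.3f, after %.3f)\n",
                sum(x$frc_validation$accepted), nrow(x$frc_validation),
                mean(x$frc_validation$frc_before), mean(x$frc_validation$frc_after)))
  }
  invisible(x)
}

#' Apply a pure per-slice operation, optionally in parallel
#'
#' Runs `op` (a function mapping a 2D slice matrix to a matrix of the same
#' shape, with no shared mutable state) over every slice. The result is
#' bitwise identical for any worker count; slices are always reassembled in
#' order.
#'
#' @param op Per-slice function `matrix -> matrix` (same shape).
#' @param stack An [image_stack()].
#' @param n_workers Number of parallel workers (forked; falls back to
#'   sequential where forking is unavailable).
#' @return The transformed [image_stack()].
#' @export
parallel_map_slices <- function(op, stack, n_workers = 1L) {
  if (!is.function(op)) stop("`op` must be a function")
  probe <- op(get_slice(stack, 0L))
  if (!is.matrix(probe) || !all(dim(probe) == dim(stack$data)[2:3])) {
    stop("`op` is not a per-slice operation: it must map a slice to a ",
         "matrix of the same shape")
  }
  map_slices(stack, op, n_workers)
}

map_slices <- function(stack, op, n_workers = 1L) {
  nz <- n_slices(stack)
  idx <- seq_len(nz) - 1L
  res <- run_list(lapply(idx, function(z) get_slice(stack, z)), op, n_workers)
  out <- stack
  for (z in seq_len(nz)) out$data[z, , ] <- res[[z]]
  out
}

run_slicewise <- function(stack, fun, n_workers = 1L) {
  idx <- seq_len(n_slices(stack)) - 1L
  run_list(lapply(idx, function(z) get_slice(stack, z)), fun, n_workers)
}

run_list <- function(items, fun, n_workers) {
  n_workers <- max(1L, as.integer(n_workers))
  if (n_workers == 1L || .Platform$OS.type == "windows") {
    lapply(items, fun)
  } else {
    res <- parallel::mclapply(items, fun, mc.cores = n_workers)
    err <- vapply(res, inherits, logical(1), "try-error")
    if (any(err)) stop("worker failure: ", attr(res[[which(err)[1]]], "condition")$message)
    res
  }
}

#' Read / write a restoration plan as YAML
#'
#' Plans serialize to a flat nested-section YAML file so every run's
#' parameters are reproducible from the report.
#'
#' @param plan A [restoration_plan()].
#' @param path YAML file path.
#' @return `plan_to_yaml` returns `path` invisibly; `plan_from_yaml`
#'   returns a `RestorationPlan`.
#' @export
plan_to_yaml <- function(plan, path) {
  yaml::write_yaml(unclass_deep(plan), path)
  invisible(path)
}

#' @rdname plan_to_yaml
#' @export
plan_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  spec <- raw$destripe$spec
  destripe <- list(enabled = isTRUE(raw$destripe$enabled),
                   spec = do.call(stripe_filter_spec, spec %||% list()))
  dp <- raw$deconvolve$params
  deconvolve <- list(enabled = isTRUE(raw$deconvolve$enabled),
                     params = do.call(deconvolution_params, dp %||% list()),
                     sigma = raw$deconvolve$sigma %||% "auto")
  ip <- raw$inpaint$params
  if (!is.null(ip$dct_smoothing_schedule)) {
    ip$dct_smoothing_schedule <- as.numeric(ip$dct_smoothing_schedule)
  }
  inpaint <- list(enabled = isTRUE(raw$inpaint$enabled),
                  params = do.call(inpaint_params, ip %||% list()))
  restoration_plan(
    charge = raw$charge %||% list(enabled = FALSE, radius = 25),
    destripe = destripe,
    align = raw$align %||% list(enabled = FALSE, levels = 3L),
    deconvolve = deconvolve,
    detect = raw$detect %||% list(enabled = TRUE, log_sigma = 2,
                                  rule = "robust_z", k = 3, cutoff = NULL),
    inpaint = inpaint,
    validate = raw$validate %||% list(enabled = TRUE, plane_range = 3),
    n_workers = raw$n_workers %||% 1L,
    seed = raw$seed %||% 1L
  )
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Serialize a restoration report to JSON
#'
#' @param report A `RestorationReport` from [run_restoration()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
report_to_json <- function(report, path) {
  out <- list(
    stages = report$stages,
    replaced_slices = report$replaced_slices,
    sharpness_before = report$quality_before$sharpness,
    sharpness_after = report$quality_after$sharpness,
    flagged = report$quality_before$flagged,
    frc_validation = report$frc_validation,
    psf_sigmas = report$psf_sigmas,
    plan = unclass_deep(report$plan)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
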