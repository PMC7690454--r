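# Single-parameter perturbation scans: every manually set parameter is
# multiplied (More) and divided (Less) by a fold factor, one parameter per
# variant. "Decreased by 50%" follows the division convention (0.1 -> 0.1 /
# 1.5 = 0.067), so More and Less are exact multiplicative inverses.

#' Manually set parameters of a network
#'
#' Parameters that are not recomputed at the population level, i.e. not the
#' target of an update rule. These are the parameters a sensitivity scan
#' perturbs.
#'
#' @param net A [bp_network()].
#' @return Character vector of parameter names.
#' @export
manual_parameters <- function(net) {
  setdiff(names(net$params), names(net$update_rules))
}

#' Build the variant list for a sensitivity scan
#'
#' @param model A [bp_model()] (or [bp_network()]).
#' @param factor Fold factor (> 1): 1.5 for the +/-50% scan, 5 for the
#'   mutation-mimicking scan.
#' @return Data frame of class `bp_variants` with one row per variant
#'   (`variant`, `param`, `direction`, `factor`, `value`) — two variants
#'   (More = multiply, Less = divide) per manually set parameter.
#' @export
make_variants <- function(model, factor = 1.5) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 1)
    stop("factor must be a single number > 1", call. = FALSE)
  net <- if (inherits(model, "bp_model")) model$network else model
  mp <- manual_parameters(net)
  base <- net$params[mp]
  out <- data.frame(
    variant = c(paste0("More_", mp), paste0("Less_", mp)),
    param = c(mp, mp),
    direction = rep(c("More", "Less"), each = length(mp)),
    factor = factor,
    value = c(base * factor, base / factor),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$param, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bp_variants", "data.frame")
  out
}

#' Run a sensitivity scan
#'
#' Runs one population simulation per variant (plus the unperturbed WT
#' reference) and records the absolute tumour population size at the
#' requested readout times. Each variant gets a deterministic seed derived
#' from the scan seed and its position, so a scan is reproducible and
#' chunkable.
#'
#' @param model A [bp_model()] with a `builder` (the variant's parameter
#'   value is fed back through the builder so that initial-composition
#'   parameters take effect).
#' @param variants A `bp_variants` table from [make_variants()] (possibly a
#'   subset of rows).
#' @param readout_times Times (hours) at which the tumour size is read out.
#' @param n_traj Particles per window.
#' @param seed Scan seed.
#' @param dt Window length (default from the model settings).
#' @param tumor_celltype Name of the cell-type predicate giving the tumour
#'   curve.
#' @return Data frame of class `bp_scan_result`: one row per variant plus a
#'   `WT` row, with columns `variant`, `param`, `direction`, `value`,
#'   `seed`, `extinct` and `tumor_<t>h` per readout time.
#' @export
run_scan <- function(model, variants, readout_times = c(220, 280),
                     n_traj = 5000, seed = 1, dt = NULL,
                     tumor_celltype = "Tumor") {
  stopifnot(inherits(model, "bp_model"))
  if (is.null(dt)) dt <- model$settings[["time_step"]]
  n_windows <- ceiling(max(readout_times) / dt)
  if (max(readout_times) > n_windows * dt)
    stop("readout times beyond the simulated horizon", call. = FALSE)

  run_one <- function(mod, run_seed) {
    tc <- run_icd(mod, dt = dt, n_windows = n_windows, n_traj = n_traj,
                  seed = run_seed)
    abs_curve <- tc$celltype_probs[, tumor_celltype] * tc$size
    sizes <- vapply(readout_times, function(t0) {
      idx <- which(tc$time >= t0)[1]
      if (is.na(idx)) 0 else abs_curve[idx]   # extinct before readout -> 0
    }, numeric(1))
    list(sizes = sizes, extinct = tc$extinct)
  }

  rows <- vector("list", nrow(variants) + 1L)
  wt_seed <- bp_derive_seed(seed, 0)
  wt <- run_one(model, wt_seed)
  rows[[1]] <- data.frame(variant = "WT", param = NA_character_,
                          direction = "WT",
                          value = NA_real_, seed = wt_seed,
                          extinct = wt$extinct, stringsAsFactors = FALSE)
  rows[[1]][sprintf("tumor_%gh", readout_times)] <- as.list(wt$sizes)

  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    vmod <- if (!is.null(model$builder))
      model$builder(stats::setNames(v$value, v$param))
    else {
      m2 <- model
      m2$network$params[[v$param]] <- v$value
      m2
    }
    v_seed <- bp_derive_seed(seed, i)
    res <- run_one(vmod, v_seed)
    row <- data.frame(variant = v$variant, param = v$param,
                      direction = v$direction, value = v$value,
                      seed = v_seed, extinct = res$extinct,
                      stringsAsFactors = FALSE)
    row[sprintf("tumor_%gh", readout_times)] <- as.list(res$sizes)
    rows[[i + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "readout_times") <- readout_times
  class(out) <- c("bp_scan_result", "data.frame")
  out
}

#' Rank scan variants by effect size
#'
#' Orders variants by the absolute difference of their tumour size from the
#' WT reference at each readout time; ties are broken lexicographically by
#' variant name, so the ranking is deterministic and invariant to the row
#' order of the input.
#'
#' @param result A `bp_scan_result` from [run_scan()].
#' @return Data frame with columns `readout`, `variant`, `param`,
#'   `direction`, `tumor_size`, `wt_size`, `delta`, `abs_delta`, `rank`,
#'   ordered by readout then decreasing `abs_delta`.
#' @export
rank_effects <- function(result) {
  stopifnot(nrow(result) > 0)
  wt <- result[result$variant == "WT", , drop = FALSE]
  if (nrow(wt) != 1L) stop("scan result must contain exactly one WT row", call. = FALSE)
  size_cols <- grep("^tumor_", names(result), value = TRUE)
  vr <- result[result$variant != "WT", , drop = FALSE]
  blocks <- lapply(size_cols, function(cl) {
    d <- data.frame(readout = sub("^tumor_", "", cl),
                    variant = vr$variant, param = vr$param,
                    direction = vr$direction,
                    tumor_size = vr[[cl]], wt_size = wt[[cl]],
                    delta = vr[[cl]] - wt[[cl]],
                    stringsAsFactors = FALSE)
    d$abs_delta <- abs(d$delta)
    d <- d[order(-d$abs_delta, d$variant), , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    d
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
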