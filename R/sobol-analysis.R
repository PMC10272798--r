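# Variance-based global sensitivity analysis of the inflation response:
# Saltelli radial design on the Sobol' sequence, batch model evaluation,
# and Saltelli-2010 / Jansen index estimators with bootstrap intervals.

#' Declare a sampled model parameter
#'
#' @param name parameter name; one of `"a"`, `"c"`, `"d"`, `"sbp"`,
#'   `"pp"`, `"hr"`, `"rate"`, `"cuff_length"`, `"arm_length"` to be
#'   understood by [run_model_batch()], or anything for generic designs.
#' @param dist `"uniform"` or `"normal"`.
#' @param ... distribution parameters: `min`, `max` for uniform (ordered,
#'   equal allowed for a degenerate fixed value), `mean`, `sd` for normal.
#' @return An object of class `parameter_spec`.
#' @examples
#' parameter_spec("pp", "normal", mean = 40, sd = 5)
#' @export
parameter_spec <- function(name, dist = c("uniform", "normal"), ...) {
  dist <- match.arg(dist)
  dots <- list(...)
  if (dist == "uniform") {
    if (is.null(dots$min) && length(dots) >= 2 && is.null(names(dots)))
      dots <- list(min = dots[[1]], max = dots[[2]])
    if (!is.numeric(dots$min) || !is.numeric(dots$max) ||
        dots$max < dots$min)
      stop("uniform spec needs ordered bounds min <= max for '", name, "'")
  } else {
    if (is.null(dots$mean) && length(dots) >= 2 && is.null(names(dots)))
      dots <- list(mean = dots[[1]], sd = dots[[2]])
    if (!is.numeric(dots$mean) || !is.numeric(dots$sd) || dots$sd <= 0)
      stop("normal spec needs mean and sd > 0 for '", name, "'")
  }
  structure(list(name = name, dist = dist, pars = dots),
            class = "parameter_spec")
}

#' The six sampled parameters of the sensitivity study
#'
#' Arterial collapse parameters `a` and `c` uniform over their clinically
#' plausible ranges, systolic and pulse pressure Gaussian around
#' normotensive values (spanning hypo- and hypertensive draws), and the
#' two protocol settings uniform over the ranges used in practice.
#'
#' @return A list of [parameter_spec()] objects.
#' @export
table2_specs <- function() {
  list(parameter_spec("a", "uniform", min = 0.017, max = 0.035),
       parameter_spec("c", "uniform", min = 0.08, max = 0.14),
       parameter_spec("sbp", "normal", mean = 125, sd = 15),
       parameter_spec("pp", "normal", mean = 40, sd = 5),
       parameter_spec("rate", "uniform", min = 4, max = 8),
       parameter_spec("cuff_length", "uniform", min = 0.10, max = 0.18))
}

spec_transform <- function(spec, u) {
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  switch(spec$dist,
         uniform = spec$pars$min + u * (spec$pars$max - spec$pars$min),
         normal = qnorm(u, spec$pars$mean, spec$pars$sd))
}

#' Saltelli sampling design for first- and total-order indices
#'
#' Draws `n` quasi-random points in `2k` dimensions from the Sobol'
#' sequence (skipping the first `n` points, which keeps the power-of-two
#' balance and avoids the origin), splits them into base matrices A and B,
#' and forms the radial blocks `AB_i` (A with column `i` replaced from B).
#' Margins are mapped by affine scaling (uniform) or the inverse normal
#' CDF. The row layout is `[A; B; AB_1; ...; AB_k]`, `n * (k + 2)` rows.
#'
#' @param specs list of [parameter_spec()] objects.
#' @param n base sample size; a power of two preserves the digital-net
#'   balance of the sequence.
#' @param seed optional integer seed for the digital shift of the
#'   sequence (see [sobol_points()]); `NULL` gives the unshifted sequence.
#' @return An object of class `sobol_design` with elements `unit` and
#'   `physical` (row-aligned matrices), `specs`, `n`, `k`, `seed`.
#' @export
sobol_design <- function(specs, n = 1024, seed = NULL) {
  stopifnot(is.list(specs), length(specs) >= 1,
            all(vapply(specs, inherits, TRUE, "parameter_spec")))
  if (n < 2) stop("base sample size n must be at least 2")
  if (bitwAnd(n, n - 1L) != 0L)
    warning("base sample size n is not a power of two; ",
            "the Sobol' balance properties are degraded")
  k <- length(specs)
  U <- sobol_points(n, 2L * k, skip = n, seed = seed)
  A <- U[, 1:k, drop = FALSE]
  B <- U[, k + 1:k, drop = FALSE]
  unit <- matrix(NA_real_, n * (k + 2L), k)
  unit[1:n, ] <- A
  unit[n + 1:n, ] <- B
  for (i in seq_len(k)) {
    ABi <- A
    ABi[, i] <- B[, i]
    unit[(i + 1L) * n + 1:n, ] <- ABi
  }
  phys <- vapply(seq_len(k),
                 function(i) spec_transform(specs[[i]], unit[, i]),
                 numeric(nrow(unit)))
  colnames(unit) <- colnames(phys) <- vapply(specs, `[[`, "", "name")
  structure(list(unit = unit, physical = phys, specs = specs, n = n,
                 k = k, seed = seed, scheme = "saltelli-radial"),
            class = "sobol_design")
}

#' @export
print.sobol_design <- function(x, ...) {
  cat(sprintf("Saltelli design: %d parameters, base n = %d, %d rows (%s)\n",
              x$k, x$n, nrow(x$physical), x$scheme))
  for (s in x$specs)
    cat(sprintf("  %-12s %s(%s)\n", s$name, s$dist,
                paste(unlist(s$pars), collapse = ", ")))
  invisible(x)
}

# map one design row onto the flat parameter list of the compiled core
row_pars <- function(base, row) {
  p <- base
  for (nm in names(row)) {
    key <- switch(nm, cuff_length = "cuff_len", arm_length = "arm_len", nm)
    if (!key %in% names(p)) stop("unknown design parameter '", nm, "'")
    p[[key]] <- row[[nm]]
  }
  # protocol maximum tracks the sampled SBP to guarantee full occlusion
  p$p_max <- p$sbp + 50
  p
}

row_valid <- function(p) {
  isTRUE(p$sbp > p$pp && p$pp > 0 && p$sbp - p$pp > p$pven_sys + 5 &&
           p$rate > 0 && p$a > 0 && p$c > 0 &&
           p$cuff_len > 0 && p$cuff_len < p$arm_len)
}

#' Run the simulator over every row of a design
#'
#' Each row is a full inflation simulation plus metric extraction, with
#' the sampled parameters overriding the reference configuration and all
#' other settings fixed. Physiologically invalid draws (e.g. diastolic
#' pressure not sufficiently above venous pressure) and failed runs are
#' recorded as missing; more than `fail_frac` missing rows aborts.
#'
#' @param design a [sobol_design()] (or any object with a `physical`
#'   matrix whose columns name model parameters).
#' @param input,protocol,circuit,geometry,tube,blood reference
#'   configuration, as in [simulate_arm()].
#' @param dt,pre_roll integration settings, as in [simulate_arm()].
#' @param ptt_tube tube law for the transit-time measurement stage. The
#'   default keeps it at the reference constants for every row: the
#'   emulated measurement chain (wave-speed calibration) does not track
#'   the sampled vessel parameters, which therefore act on the PTT/PAT
#'   metrics only through the simulated pressures. Pass `NULL` to use
#'   each row's sampled tube law instead.
#' @param fail_frac maximum tolerated fraction of failed rows.
#' @return A matrix, rows aligned with the design, with the six metric
#'   columns; failed rows are `NA`. Attribute `failed` lists their
#'   indices.
#' @export
run_model_batch <- function(design, input = systemic_input(),
                            protocol = cuff_protocol(),
                            circuit = circuit_params(),
                            geometry = arm_geometry(),
                            tube = tube_law(),
                            blood = blood_properties(),
                            dt = 5e-4, pre_roll = 10,
                            ptt_tube = tube_law(), fail_frac = 0.01) {
  X <- design$physical
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  protocol <- resolve_protocol(protocol, input)
  base <- sim_pars(input, protocol, circuit, geometry, tube, blood,
                   pre_roll, "euler")
  out <- matrix(NA_real_, nrow(X), length(.METRIC_COLS),
                dimnames = list(NULL, .METRIC_COLS))
  failed <- integer(0)
  for (r in seq_len(nrow(X))) {
    p <- row_pars(base, X[r, ])
    if (!row_valid(p)) {
      failed <- c(failed, r)
      next
    }
    m <- tryCatch({
      core <- .sim_core(p, dt, FALSE)
      inp <- systemic_input(p$sbp, p$pp, p$hr, p$pven_sys)
      prot <- cuff_protocol(p$rate, p$t_start, p$p_max, p$hold)
      geo <- arm_geometry(p$arm_len, p$cuff_len)
      tl <- tube_law(p$a, p$c, p$d)
      beats <- beats_from_core(core, inp, prot)
      ptt <- ptt_from_beats(beats, geo, if (is.null(ptt_tube)) tl else
        ptt_tube, blood, inp)
      mm <- metrics_from_beats(beats, ptt, core$p_end, core$slope_end, inp,
                               geo$arm_length - geo$cuff_length,
                               core$pulse_end)
      unlist(mm[.METRIC_COLS])
    }, error = function(e) NULL)
    if (is.null(m) || anyNA(m)) failed <- c(failed, r) else out[r, ] <- m
  }
  if (length(failed) > fail_frac * nrow(X))
    stop(sprintf("%d of %d design rows failed (> %.1f%% tolerated)",
                 length(failed), nrow(X), 100 * fail_frac))
  if (length(failed))
    message(length(failed), " design row(s) failed or invalid: ",
            paste(utils::head(failed, 10), collapse = ", "))
  attr(out, "failed") <- failed
  out
}

#' Sobol indices from a Saltelli design and its model outputs
#'
#' First-order indices by the Saltelli-2010 estimator
#' \eqn{S_i = \mathrm{mean}(f_B (f_{AB_i} - f_A)) / V(Y)} and total-order
#' indices by the Jansen estimator
#' \eqn{S_{Ti} = \mathrm{mean}((f_A - f_{AB_i})^2) / (2 V(Y))}, with
#' `V(Y)` the variance of the pooled A and B evaluations. Confidence
#' half-widths come from bootstrap resampling of the base sample rows.
#' Rows with missing output are dropped pairwise across all blocks.
#'
#' @param design the [sobol_design()] the outputs were computed on.
#' @param outputs numeric matrix (rows aligned with the design; one
#'   column per model output) or vector.
#' @param n_boot bootstrap replicates for the confidence half-widths.
#' @param seed integer seed for the bootstrap.
#' @param clip_negative clip small negative index estimates at zero in
#'   the reported tables (raw estimates are kept alongside).
#' @return An object of class `sobol_result`: matrices `S1`, `ST`,
#'   `S1_ci`, `ST_ci` (parameters x outputs), raw counterparts, variance
#'   `V`, and metadata.
#' @export
sobol_indices <- function(design, outputs, n_boot = 100, seed = 1,
                          clip_negative = TRUE) {
  stopifnot(inherits(design, "sobol_design"))
  Y <- as.matrix(outputs)
  n <- design$n
  k <- design$k
  if (nrow(Y) != n * (k + 2L))
    stop("outputs have ", nrow(Y), " rows; design expects ", n * (k + 2L))
  if (is.null(colnames(Y)))
    colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  pnames <- vapply(design$specs, `[[`, "", "name")
  m <- ncol(Y)
  ok <- rep(TRUE, n)
  for (b in seq_len(k + 2L))
    ok <- ok & stats::complete.cases(Y[(b - 1L) * n + 1:n, , drop = FALSE])
  if (sum(ok) < 8) stop("too few complete design rows for estimation")
  est <- function(idx) {
    fA <- Y[idx, , drop = FALSE]
    fB <- Y[n + idx, , drop = FALSE]
    S1 <- ST <- matrix(NA_real_, k, m)
    V <- apply(rbind(fA, fB), 2, function(v) mean(v^2) - mean(v)^2)
    for (i in seq_len(k)) {
      fAB <- Y[(i + 1L) * n + idx, , drop = FALSE]
      S1[i, ] <- colMeans(fB * (fAB - fA)) / V
      ST[i, ] <- colMeans((fA - fAB)^2) / (2 * V)
    }
    list(S1 = S1, ST = ST, V = V)
  }
  idx0 <- which(ok)
  e <- est(idx0)
  if (any(e$V < .Machine$double.eps * 100))
    stop("an output has (near-)zero variance; its indices are undefined")
  boots <- with_seed(seed, replicate(n_boot, {
    e_b <- est(sample(idx0, length(idx0), replace = TRUE))
    c(e_b$S1, e_b$ST)
  }))
  ci <- 1.96 * apply(boots, 1, sd)
  S1_ci <- matrix(ci[seq_len(k * m)], k, m)
  ST_ci <- matrix(ci[k * m + seq_len(k * m)], k, m)
  dn <- list(pnames, colnames(Y))
  dimnames(e$S1) <- dimnames(e$ST) <- dimnames(S1_ci) <-
    dimnames(ST_ci) <- dn
  structure(list(
    S1 = if (clip_negative) pmax(e$S1, 0) else e$S1,
    ST = if (clip_negative) pmax(e$ST, 0) else e$ST,
    S1_raw = e$S1, ST_raw = e$ST, S1_ci = S1_ci, ST_ci = ST_ci,
    V = setNames(e$V, colnames(Y)), n = n, n_used = length(idx0),
    n_boot = n_boot, seed = seed,
    estimators = c(S1 = "saltelli-2010", ST = "jansen")),
    class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Sobol sensitivity indices (base n = %d, %d complete; S1 %s, ST %s)\n",
    x$n, x$n_used, x$estimators["S1"], x$estimators["ST"]))
  m <- ncol(x$S1)
  wide <- matrix("", nrow(x$S1), 2 * m,
                 dimnames = list(rownames(x$S1),
                                 paste(rep(colnames(x$S1), each = 2),
                                       c("S1", "ST"))))
  wide[, seq(1, 2 * m, 2)] <- format(round(x$S1, digits))
  wide[, seq(2, 2 * m, 2)] <- format(round(x$ST, digits))
  print(wide, quote = FALSE)
  invisible(x)
}

#' @export
plot.sobol_result <- function(x, output = colnames(x$S1)[1], ...) {
  h <- rbind(x$S1[, output], x$ST[, output])
  barplot(h, beside = TRUE, names.arg = rownames(x$S1),
          legend.text = c("S1", "ST"), ylab = "Sobol index",
          main = output, ...)
  invisible(x)
}

#' Full sensitivity analysis: design, batch run, indices
#'
#' @param specs list of [parameter_spec()]s; defaults to the six-parameter
#'   study space of [table2_specs()].
#' @param n base sample size (total model runs `n * (k + 2)`).
#' @param seed integer seed (digital shift of the sequence + bootstrap).
#' @param n_boot bootstrap replicates.
#' @param ... reference configuration passed to [run_model_batch()].
#' @return An object of class `sobol_analysis`: `design`, `outputs`,
#'   `result`.
#' @export
run_sobol_analysis <- function(specs = table2_specs(), n = 1024, seed = 1,
                               n_boot = 100, ...) {
  design <- sobol_design(specs, n, seed)
  outputs <- run_model_batch(design, ...)
  result <- sobol_indices(design, outputs, n_boot = n_boot, seed = seed)
  structure(list(design = design, outputs = outputs, result = result),
            class = "sobol_analysis")
}

#' @export
print.sobol_analysis <- function(x, ...) {
  print(x$design)
  print(x$result, ...)
  invisible(x)
}

#' Indices in long-format table
#'
#' @param x a `sobol_result` or `sobol_analysis`.
#' @param ... unused.
#' @return Data frame with `parameter`, `output`, `S1`, `ST` and their
#'   confidence half-widths.
#' @export
sobol_table <- function(x, ...) {
  if (inherits(x, "sobol_analysis")) x <- x$result
  stopifnot(inherits(x, "sobol_result"))
  g <- expand.grid(parameter = rownames(x$S1), output = colnames(x$S1),
                   stringsAsFactors = FALSE)
  g$S1 <- as.vector(x$S1)
  g$S1_ci <- as.vector(x$S1_ci)
  g$ST <- as.vector(x$ST)
  g$ST_ci <- as.vector(x$ST_ci)
  g
}
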