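#' Specification of one study group for the cohort generator
#'
#' Holds the per-group sample size and the normal-distribution parameters of
#' the four measured diameters: retinal arteriolar outer/lumen diameter
#' (RAOD/RALD) and retinal venular outer/lumen diameter (RVOD/RVLD), in
#' micrometres.
#'
#' Within one vessel the outer and lumen diameters are strongly coupled --
#' a vessel with a wide outer wall also has a wide lumen, and the wall
#' thickness varies far less than either diameter. The generator therefore
#' draws each (outer, lumen) pair from a bivariate normal whose correlation
#' is chosen to reproduce a target wall-thickness SD
#' (`sd_awt`, `sd_vwt`): since WT = (OD - LD)/2,
#' `rho = (sd_od^2 + sd_ld^2 - 4 sd_wt^2) / (2 sd_od sd_ld)`.
#' When the wall-thickness SDs are `NULL` the diameters are drawn
#' independently (`rho = 0`).
#'
#' @param group_label group name, conventionally one of `"GDM"`, `"PC"`,
#'   `"NC"` (gestational diabetes, pregnant control, normal control).
#' @param n_subjects number of subjects (> 0).
#' @param mean_raod,sd_raod,mean_rald,sd_rald arteriolar outer/lumen
#'   diameter mean and SD (um).
#' @param mean_rvod,sd_rvod,mean_rvld,sd_rvld venular outer/lumen diameter
#'   mean and SD (um).
#' @param sd_awt,sd_vwt target wall-thickness SDs (um) used to derive the
#'   within-vessel correlation; `NULL` for independent draws.
#' @param seed integer seed for this group's draws (optional).
#' @return an object of class `group_spec`.
#' @seealso [reference_group_specs()] for the built-in reference cohort.
#' @export
group_spec <- function(group_label, n_subjects,
                       mean_raod, sd_raod, mean_rald, sd_rald,
                       mean_rvod, sd_rvod, mean_rvld, sd_rvld,
                       sd_awt = NULL, sd_vwt = NULL, seed = NULL) {
  stopifnot(is.character(group_label), length(group_label) == 1L,
            n_subjects > 0)
  sds <- c(sd_raod, sd_rald, sd_rvod, sd_rvld, sd_awt, sd_vwt)
  if (any(sds < 0)) stop("all SDs must be non-negative")
  spec <- list(group_label = group_label, n_subjects = as.integer(n_subjects),
               mean_raod = mean_raod, sd_raod = sd_raod,
               mean_rald = mean_rald, sd_rald = sd_rald,
               mean_rvod = mean_rvod, sd_rvod = sd_rvod,
               mean_rvld = mean_rvld, sd_rvld = sd_rvld,
               sd_awt = sd_awt, sd_vwt = sd_vwt, seed = seed)
  # fail early on infeasible geometry or correlation
  check_feasible(spec)
  rho_from_wall_sd(sd_raod, sd_rald, sd_awt)
  rho_from_wall_sd(sd_rvod, sd_rvld, sd_vwt)
  structure(spec, class = "group_spec")
}

check_feasible <- function(spec) {
  gap_a <- spec$mean_rald - spec$mean_raod
  gap_v <- spec$mean_rvld - spec$mean_rvod
  if (gap_a > 3 * sqrt(spec$sd_raod^2 + spec$sd_rald^2) ||
      gap_v > 3 * sqrt(spec$sd_rvod^2 + spec$sd_rvld^2)) {
    stop("infeasible group spec: mean lumen exceeds mean outer diameter ",
         "by more than 3 SD")
  }
  invisible(spec)
}

rho_from_wall_sd <- function(sd_od, sd_ld, sd_wt) {
  if (is.null(sd_wt) || sd_od == 0 || sd_ld == 0) return(0)
  rho <- (sd_od^2 + sd_ld^2 - 4 * sd_wt^2) / (2 * sd_od * sd_ld)
  if (rho < -1 || rho > 1) {
    stop(sprintf(
      "wall-thickness SD %.4g is incompatible with diameter SDs %.4g/%.4g",
      sd_wt, sd_od, sd_ld))
  }
  rho
}

#' Reference cohort summary statistics (means and SDs)
#'
#' The published three-group reference values this package's generator and
#' tests are calibrated against: per-group means and SDs of the eleven
#' vessel parameters for a gestational-diabetes (GDM) group (n = 50), a
#' pregnant control group (PC, n = 55) and a non-pregnant normal control
#' group (NC, n = 55). Units are micrometres for diameters and wall
#' thickness, square micrometres for wall cross-sectional area; the ratios
#' are dimensionless.
#'
#' The two published summary tables disagree on the NC arteriovenous ratio
#' (0.7676 +- 0.0588 on the arterial side versus 0.7498 +- 0.0622 on the
#' venular side); the arterial-side value is carried here and the
#' discrepancy is not silently reconciled.
#'
#' @return a data frame with columns `parameter`, `group`, `n`, `mean`,
#'   `sd`.
#' @export
reference_group_stats <- function() {
  g <- c("GDM", "PC", "NC")
  n <- c(50L, 55L, 55L)
  row <- function(parameter, means, sds) {
    data.frame(parameter = parameter, group = g, n = n,
               mean = means, sd = sds, stringsAsFactors = FALSE)
  }
  rbind(
    row("RAOD",  c(122.0836, 123.1346, 123.6113), c(10.2104, 11.6011,  9.6959)),
    row("RALD",  c( 94.5531,  95.6198,  96.9295), c(10.5105, 11.8401,  9.1238)),
    row("AWT",   c( 13.7653,  13.7574,  13.3409), c( 1.4279,  1.4343,  1.6942)),
    row("AWLR",  c(  0.1478,   0.1464,   0.1388), c( 0.0250,  0.0253,  0.0218)),
    row("AWCSA", c(4677.0571, 4720.5964, 4627.5738),
                 c(630.3685, 678.4434, 753.9919)),
    row("RVOD",  c(168.2741, 163.5744, 161.1570), c(10.2512,  8.0235,  7.1684)),
    row("RVLD",  c(142.9281, 139.3810, 137.6394), c( 9.7501,  7.7640,  6.7744)),
    row("VWT",   c( 12.6730,  12.0967,  11.7588), c( 0.9874,  1.1046,  1.1479)),
    row("VWLR",  c(  0.0890,   0.0870,   0.0856), c( 0.0084,  0.0095,  0.0094)),
    row("VWCSA", c(6199.5769, 5756.8380, 5520.3974),
                 c(686.2176, 634.0372, 637.0054)),
    row("AVR",   c(  0.7262,   0.7534,   0.7676), c( 0.0525,  0.0678,  0.0588))
  )
}

#' Group specs reproducing the reference cohort
#'
#' Builds the three [group_spec()]s whose diameter means/SDs and
#' wall-thickness SDs equal the reference summary statistics from
#' [reference_group_stats()], with n = 50/55/55.
#'
#' @param seeds optional integer vector of length 3 with per-group seeds.
#' @return a list of three `group_spec`s, in order GDM, PC, NC.
#' @export
reference_group_specs <- function(seeds = NULL) {
  st <- reference_group_stats()
  pick <- function(p, grp, what) st[st$parameter == p & st$group == grp, what]
  groups <- c("GDM", "PC", "NC")
  lapply(seq_along(groups), function(i) {
    grp <- groups[i]
    group_spec(
      group_label = grp,
      n_subjects = pick("RAOD", grp, "n"),
      mean_raod = pick("RAOD", grp, "mean"), sd_raod = pick("RAOD", grp, "sd"),
      mean_rald = pick("RALD", grp, "mean"), sd_rald = pick("RALD", grp, "sd"),
      mean_rvod = pick("RVOD", grp, "mean"), sd_rvod = pick("RVOD", grp, "sd"),
      mean_rvld = pick("RVLD", grp, "mean"), sd_rvld = pick("RVLD", grp, "sd"),
      sd_awt = pick("AWT", grp, "sd"), sd_vwt = pick("VWT", grp, "sd"),
      seed = if (!is.null(seeds)) seeds[i] else NULL)
  })
}

draw_pair <- function(n, mean_od, sd_od, mean_ld, sd_ld, rho) {
  od <- ld <- numeric(n)
  need <- seq_len(n)
  for (iter in 1:1000) {
    m <- length(need)
    z1 <- stats::rnorm(m); z2 <- stats::rnorm(m)
    od[need] <- mean_od + sd_od * z1
    ld[need] <- mean_ld + sd_ld * (rho * z1 + sqrt(1 - rho^2) * z2)
    need <- which(!(od > ld & ld > 0))
    if (length(need) == 0L) return(cbind(od = od, ld = ld))
  }
  stop("rejection sampling failed: outer > lumen > 0 essentially never holds")
}

#' Generate a synthetic three-group cohort
#'
#' Draws per-subject (outer, lumen) diameter pairs for one artery and one
#' vein per eye from the per-group bivariate normal described in
#' [group_spec()], rejection-resampling any draw that violates
#' `outer > lumen > 0` (rejection keeps the marginals near-normal instead
#' of clipping them), then fills in the seven derived parameters with
#' [compute_params()].
#'
#' @param specs a list of [group_spec()]s with unique labels.
#' @param seed master seed; a `seed` carried by an individual spec takes
#'   precedence for that group's draws.
#' @param pi_tilde circle constant forwarded to [compute_params()].
#' @return a `cohort_table`: a data frame with columns `subject_id`,
#'   `group`, `eye` and the eleven parameters `RAOD, RALD, RVOD, RVLD,
#'   AWT, VWT, AWLR, VWLR, AWCSA, VWCSA, AVR`.
#' @examples
#' coh <- generate_cohort(reference_group_specs(), seed = 1)
#' aggregate(VWT ~ group, coh, mean)
#' @export
generate_cohort <- function(specs, seed = NULL, pi_tilde = 3.14) {
  if (inherits(specs, "group_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "group_spec")))
  labels <- vapply(specs, `[[`, character(1), "group_label")
  if (anyDuplicated(labels)) stop("group labels must be unique")

  gen_one <- function(spec) {
    check_feasible(spec)
    rho_a <- rho_from_wall_sd(spec$sd_raod, spec$sd_rald, spec$sd_awt)
    rho_v <- rho_from_wall_sd(spec$sd_rvod, spec$sd_rvld, spec$sd_vwt)
    art <- draw_pair(spec$n_subjects, spec$mean_raod, spec$sd_raod,
                     spec$mean_rald, spec$sd_rald, rho_a)
    ven <- draw_pair(spec$n_subjects, spec$mean_rvod, spec$sd_rvod,
                     spec$mean_rvld, spec$sd_rvld, rho_v)
    pars <- compute_params(art[, "od"], art[, "ld"],
                           ven[, "od"], ven[, "ld"], pi_tilde = pi_tilde)
    cbind(data.frame(
      subject_id = sprintf("%s_%03d", spec$group_label,
                           seq_len(spec$n_subjects)),
      group = spec$group_label, eye = "right",
      stringsAsFactors = FALSE), pars)
  }

  run <- function() {
    do.call(rbind, lapply(specs, function(spec) {
      if (!is.null(spec$seed)) set.seed(spec$seed)
      gen_one(spec)
    }))
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out$group <- factor(out$group, levels = labels)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write / read a cohort table as CSV
#'
#' @param cohort a `cohort_table` (or compatible data frame).
#' @param path CSV file path.
#' @return `write_cohort` returns the path invisibly; `read_cohort`
#'   returns a `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "group", "RAOD", "RALD", "RVOD", "RVLD")
  missing <- setdiff(needed, names(out))
  if (length(missing)) {
    stop("cohort CSV lacks required columns: ", paste(missing, collapse = ", "))
  }
  out$group <- factor(out$group, levels = unique(out$group))
  class(out) <- c("cohort_table", "data.frame")
  out
}
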