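#' Measure ASPECTS regions against the mirrored hemisphere
#'
#' The automated stand-in for a radiologist's hypoattenuation call: for
#' every region and side, the mean HU inside the region mask is compared
#' with the mean inside the mirror-image mask on the contralateral
#' hemisphere. A negative difference means the region is hypoattenuated
#' relative to its mirror.
#'
#' @param slice a [ct_slice()] with the same shape as the template.
#' @param template an [aspects_template()].
#' @return A data frame with columns `region` (code), `name`, `side`,
#'   `mean_hu`, `contralateral_mean_hu`, `difference`.
#' @export
measure_regions <- function(slice, template) {
  stopifnot(inherits(slice, "ct_slice"),
            inherits(template, "aspects_template"))
  px <- slice$pixels
  if (!all(dim(px) == template$shape))
    stop("slice and template shapes differ", call. = FALSE)
  mirrored <- mirror_lr(px)
  lab <- template$labels
  colidx <- matrix(seq_len(ncol(lab)), nrow(lab), ncol(lab), byrow = TRUE)
  codes <- sort(unique(lab[lab > 0]))
  rows <- list()
  for (code in codes) {
    for (side in c("left", "right")) {
      m <- lab == code & (if (side == "right") colidx > template$midline_col
                          else colidx < template$midline_col)
      if (!any(m))
        stop(sprintf("empty region mask: %s (%s)", region_name(code), side),
             call. = FALSE)
      mu <- mean(px[m])
      contra <- mean(mirrored[m])
      rows[[length(rows) + 1L]] <-
        data.frame(region = code, name = region_name(code), side = side,
                   mean_hu = mu, contralateral_mean_hu = contra,
                   difference = mu - contra)
    }
  }
  do.call(rbind, rows)
}

#' Flag hypoattenuated regions
#'
#' A region/side is flagged when its mirror difference is at or below
#' `-threshold_hu`. The same rule is applied to unprocessed and
#' BC-processed images; because BC amplifies low-frequency differences, it
#' raises both true and false flags — the sensitivity/specificity trade-off
#' the blending produces.
#'
#' @param readings output of [measure_regions()].
#' @param threshold_hu positive detection threshold on the region-mean
#'   difference, HU. Default 1.5 HU.
#' @return Subset of `readings` rows that are flagged.
#' @export
detect_regions <- function(readings, threshold_hu = 1.5) {
  stopifnot_scalar_num(threshold_hu, "threshold_hu", positive = TRUE)
  readings[readings$difference <= -threshold_hu, , drop = FALSE]
}

#' ASPECTS from a set of affected regions
#'
#' ASPECTS awards one point per unaffected MCA region: a normal study
#' scores 10, and each distinct affected region subtracts one.
#'
#' @param detected integer vector of affected region codes (a
#'   [detect_regions()] result is also accepted; its distinct region codes
#'   are used).
#' @return Integer score 0-10.
#' @examples
#' aspects_score(integer(0))     # 10: no measurable hypoattenuation
#' aspects_score(c(2, 3))        # insula + lentiform -> 8
#' @export
aspects_score <- function(detected) {
  if (is.data.frame(detected)) detected <- detected$region
  detected <- unique(as.integer(detected))
  if (length(detected) > 0 && !all(detected %in% .region_codes))
    stop("unknown region code(s) in 'detected'", call. = FALSE)
  max(0L, 10L - length(detected))
}

#' Hypoattenuated area of a slice
#'
#' Automated surrogate for the freehand-ROI area measurement: the
#' left-right mirror difference image is lightly smoothed, thresholded at
#' `-threshold_hu` inside the brain mask, and the surviving connected
#' components (those at least `min_area_cm2` large, to reject isolated
#' noise pixels) are summed into an area in cm^2.
#'
#' @param slice a [ct_slice()].
#' @param template an [aspects_template()] providing the brain mask and
#'   midline.
#' @param threshold_hu detection threshold on the smoothed difference, HU.
#' @param smooth_mm Gaussian smoothing of the difference image before
#'   thresholding, mm.
#' @param min_area_cm2 minimum connected-component area retained.
#' @return Area in cm^2 (0 when nothing is flagged).
#' @export
lesion_area <- function(slice, template, threshold_hu = 1.5,
                        smooth_mm = 1.5, min_area_cm2 = 0.1) {
  stopifnot(inherits(slice, "ct_slice"),
            inherits(template, "aspects_template"))
  stopifnot_scalar_num(threshold_hu, "threshold_hu", positive = TRUE)
  px <- slice$pixels
  d <- px - mirror_lr(px)
  if (smooth_mm > 0) d <- gaussian_lowpass(d, smooth_mm / slice$spacing)
  flag <- d <= -threshold_hu & template$brain_mask
  if (!any(flag)) return(0)
  comp <- EBImage::bwlabel(flag * 1)
  px_area_cm2 <- prod(slice$spacing) / 100
  sizes <- tabulate(comp[comp > 0])
  keep <- sizes[sizes * px_area_cm2 >= min_area_cm2]
  sum(keep) * px_area_cm2
}

#' Contrast-to-noise ratio between a lesion and its mirror
#'
#' \eqn{\mathrm{CNR} = |\bar{x}_{lesion} - \bar{x}_{mirror}| /
#' \mathrm{sd}(x_{mirror})}: the lesion-to-background mean attenuation
#' difference in units of background noise. Used to quantify how much more
#' conspicuous a lesion is after BC processing.
#'
#' @param slice a [ct_slice()].
#' @param lesion_mask,mirror_mask disjoint non-empty logical matrices.
#' @return Dimensionless CNR.
#' @export
cnr <- function(slice, lesion_mask, mirror_mask) {
  px <- if (inherits(slice, "ct_slice")) slice$pixels else slice
  if (!any(lesion_mask) || !any(mirror_mask))
    stop("masks must be non-empty", call. = FALSE)
  if (any(lesion_mask & mirror_mask))
    stop("masks must be disjoint", call. = FALSE)
  s <- stats::sd(px[mirror_mask])
  if (s == 0) stop("sd of mirror region is zero: CNR undefined",
                   call. = FALSE)
  abs(mean(px[lesion_mask]) - mean(px[mirror_mask])) / s
}

#' Run the NECT-vs-BC reading experiment on a cohort
#'
#' Reproduces the study design on synthetic data: every phantom is read
#' twice with the same mirror-comparison rule — once unprocessed ("NECT")
#' and once after [apply_bc()] ("BC") — and both readings are scored
#' against the generator's ground truth. A patient counts as positive when
#' at least one region/side is flagged. Region/side detections are matched
#' to true lesion locations for the per-region miss tally.
#'
#' @param cohort a [make_cohort()] result.
#' @param params a [bc_params()].
#' @param threshold_hu reading threshold, HU (see [detect_regions()]).
#' @return An object of class `bc_experiment`: list with `confusion`
#'   (per-method [confusion2x2()]), `accuracy` (per-method
#'   [diagnostic_accuracy()]), `misses` (per-region counts of true lesions
#'   missed by each method), `patients` (per-patient data frame with
#'   ASPECTS under both readings), `threshold_hu`, `params`.
#' @export
run_experiment <- function(cohort, params = bc_params(), threshold_hu = 1.5) {
  stopifnot(inherits(cohort, "ct_cohort"), inherits(params, "bc_params"))
  template <- attr(cohort, "template")
  counts <- list(nect = c(tp = 0L, fp = 0L, fn = 0L, tn = 0L),
                 bc = c(tp = 0L, fp = 0L, fn = 0L, tn = 0L))
  miss <- matrix(0L, nrow = length(.region_codes), ncol = 2,
                 dimnames = list(names(.region_codes), c("nect", "bc")))
  n_true <- setNames(integer(length(.region_codes)), names(.region_codes))
  pat <- vector("list", length(cohort))

  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    truth_pos <- length(p$truth$left) + length(p$truth$right) > 0
    det <- list(
      nect = detect_regions(measure_regions(p$slice, template), threshold_hu),
      bc = detect_regions(measure_regions(apply_bc(p$slice, params),
                                          template), threshold_hu))
    for (method in c("nect", "bc")) {
      pos <- nrow(det[[method]]) > 0
      cell <- if (truth_pos && pos) "tp" else if (!truth_pos && pos) "fp"
        else if (truth_pos && !pos) "fn" else "tn"
      counts[[method]][cell] <- counts[[method]][cell] + 1L
    }
    for (side in c("left", "right")) {
      for (code in p$truth[[side]]) {
        nm <- region_name(code)
        n_true[nm] <- n_true[nm] + 1L
        for (method in c("nect", "bc")) {
          hit <- any(det[[method]]$region == code &
                       det[[method]]$side == side)
          if (!hit) miss[nm, method] <- miss[nm, method] + 1L
        }
      }
    }
    pat[[i]] <- data.frame(
      patient_id = p$patient_id, truth_positive = truth_pos,
      nect_positive = nrow(det$nect) > 0, bc_positive = nrow(det$bc) > 0,
      aspects_nect = aspects_score(det$nect),
      aspects_bc = aspects_score(det$bc))
  }
  conf <- lapply(counts, function(ct)
    confusion2x2(ct["tp"], ct["fp"], ct["fn"], ct["tn"]))
  structure(list(
    confusion = conf,
    accuracy = lapply(conf, diagnostic_accuracy),
    misses = data.frame(region = rownames(miss),
                        n_lesions = as.integer(n_true),
                        nect_missed = as.integer(miss[, "nect"]),
                        bc_missed = as.integer(miss[, "bc"]),
                        row.names = NULL),
    patients = do.call(rbind, pat),
    threshold_hu = threshold_hu, params = params),
    class = "bc_experiment")
}

#' @export
print.bc_experiment <- function(x, ...) {
  cat("<bc_experiment>\n")
  for (m in c("nect", "bc")) {
    a <- x$accuracy[[m]]
    cat(sprintf(
      "  %-4s sens %3d%%  spec %3d%%  ppv %3d%%  npv %3d%%  acc %3d%%\n",
      toupper(m), a$percent[["sensitivity"]], a$percent[["specificity"]],
      a$percent[["ppv"]], a$percent[["npv"]], a$percent[["accuracy"]]))
  }
  cat(sprintf("  reading threshold %.2f HU\n", x$threshold_hu))
  invisible(x)
}
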