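# ASPECTS region codes used throughout the package
.region_codes <- c(caudate = 1L, insula = 2L, lentiform = 3L,
                   internal_capsule = 4L, M1 = 5L, M2 = 6L, M3 = 7L,
                   M4 = 8L, M5 = 9L, M6 = 10L)

# tissue class codes of the phantom label map
.tissue_codes <- c(air = 0L, skull = 1L, csf = 2L, white = 3L,
                   gray = 4L, deep_gray = 5L)

#' ASPECTS region names and codes
#'
#' The ten middle-cerebral-artery territory regions scored by ASPECTS:
#' caudate, insula, lentiform, internal capsule and the six cortical
#' sectors M1-M6. Codes 1-7 live on the ganglionic slice, 8-10 on the
#' supraganglionic slice.
#'
#' @return Named integer vector mapping region name to code.
#' @export
aspects_regions <- function() .region_codes

region_name <- function(code) names(.region_codes)[match(code, .region_codes)]

resolve_region <- function(region) {
  if (is.character(region)) {
    code <- .region_codes[match(region, names(.region_codes))]
    if (is.na(code)) stop(sprintf("unknown region '%s'", region),
                          call. = FALSE)
    unname(code)
  } else {
    code <- as.integer(region)
    if (!code %in% .region_codes)
      stop(sprintf("unknown region code %d", code), call. = FALSE)
    code
  }
}

#' Build the stylized ASPECTS region template
#'
#' A deterministic, exactly mirror-symmetric single-slice label map of the
#' MCA territory: an elliptical brain inside a skull ring, lateral
#' ventricles, and — at the ganglionic level — caudate, lentiform, internal
#' capsule, insular ribbon and the cortical sectors M1-M3; at the
#' supraganglionic level the cortical sectors M4-M6. The geometry is
#' parametric (fractions of the image shape), not anatomical: it exists so
#' that ground truth and left/right mirroring are exact.
#'
#' @param level `"ganglionic"` or `"supraganglionic"`.
#' @param shape integer length-2, image size in pixels; at least 128 x 128
#'   with an even number of columns (so the sagittal midline falls between
#'   two columns and mirroring is exact).
#' @param spacing pixel size in mm; default scales a 220 mm field of view to
#'   `shape`.
#' @return An object of class `aspects_template` with fields `labels`
#'   (integer matrix of region codes, 0 = no region), `tissue` (tissue
#'   class matrix), `brain_mask`, `level`, `midline_col`, `spacing`.
#' @examples
#' tpl <- aspects_template("ganglionic", shape = c(128, 128))
#' table(tpl$labels[tpl$labels > 0])
#' @export
aspects_template <- function(level = c("ganglionic", "supraganglionic"),
                             shape = c(256L, 256L), spacing = NULL) {
  level <- match.arg(level)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 128L))
    stop("'shape' must be at least 128 x 128 pixels", call. = FALSE)
  if (shape[2] %% 2L != 0L)
    stop("'shape' must have an even number of columns", call. = FALSE)
  if (is.null(spacing)) spacing <- 220 / shape
  H <- shape[1]; W <- shape[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  Y <- matrix(seq_len(H), H, W)
  U <- abs(matrix(seq_len(W), H, W, byrow = TRUE) - cx)  # lateral offset, px
  right <- matrix(seq_len(W), H, W, byrow = TRUE) > cx

  ell <- function(u0, y0, au, ay)
    ((U - u0) / au)^2 + ((Y - y0) / ay)^2 <= 1

  head <- ell(0, cy, 0.385 * W, 0.455 * H)
  brain <- ell(0, cy, 0.350 * W, 0.420 * H)
  skull <- head & !brain
  vent <- if (level == "ganglionic")
    ell(0.045 * W, cy - 0.02 * H, 0.025 * W, 0.080 * H)
  else
    ell(0.040 * W, cy - 0.02 * H, 0.020 * W, 0.055 * H)
  vent <- vent & brain

  # normalized brain radius and MCA sector angle (0 = anterior midline)
  rn <- sqrt((U / (0.350 * W))^2 + ((Y - cy) / (0.420 * H))^2)
  phi <- atan2(U, -(Y - cy))
  ribbon <- brain & rn >= 0.78 & rn <= 1
  sec <- list(c(15, 65), c(65, 115), c(115, 165))  # degrees from anterior

  labels <- matrix(0L, H, W)
  tissue <- matrix(.tissue_codes[["air"]], H, W)
  tissue[skull] <- .tissue_codes[["skull"]]
  tissue[brain] <- .tissue_codes[["white"]]
  tissue[ribbon] <- .tissue_codes[["gray"]]
  tissue[vent] <- .tissue_codes[["csf"]]

  base_code <- if (level == "ganglionic") 5L else 8L
  for (k in 1:3) {
    m <- ribbon & phi > sec[[k]][1] * pi / 180 & phi <= sec[[k]][2] * pi / 180
    labels[m] <- base_code + k - 1L
  }

  if (level == "ganglionic") {
    caud <- ell(0.085 * W, cy - 0.075 * H, 0.028 * W, 0.045 * H) & brain & !vent
    lent <- ell(0.155 * W, cy - 0.005 * H, 0.038 * W, 0.060 * H) & brain
    ic <- ell(0.118 * W, cy - 0.040 * H, 0.020 * W, 0.050 * H) & brain &
      !caud & !lent & !vent
    ins <- ell(0.225 * W, cy - 0.005 * H, 0.018 * W, 0.065 * H) & brain
    labels[caud] <- .region_codes[["caudate"]]
    labels[lent] <- .region_codes[["lentiform"]]
    labels[ic] <- .region_codes[["internal_capsule"]]
    labels[ins] <- .region_codes[["insula"]]
    tissue[caud | lent] <- .tissue_codes[["deep_gray"]]
    tissue[ins] <- .tissue_codes[["gray"]]
    tissue[ic] <- .tissue_codes[["white"]]
  }

  structure(list(labels = labels, tissue = tissue, brain_mask = brain,
                 level = level, midline_col = cx, spacing = spacing,
                 shape = shape),
            class = "aspects_template")
}

#' @export
print.aspects_template <- function(x, ...) {
  codes <- sort(unique(x$labels[x$labels > 0]))
  cat(sprintf("<aspects_template> %s level, %d x %d px, regions: %s\n",
              x$level, x$shape[1], x$shape[2],
              paste(region_name(codes), collapse = ", ")))
  invisible(x)
}

#' Phantom configuration
#'
#' Tissue attenuations, the noise model and the seed for a synthetic brain
#' CT slice. Defaults use standard adult-brain CT attenuations (white
#' matter 28 HU, cortical gray 38 HU, deep gray nuclei 40 HU, CSF 8 HU,
#' skull 800 HU) and additive Gaussian noise of 4 HU — the regime where a
#' 30 HU blending center sits between the white and gray means.
#'
#' @param shape,spacing image geometry, as in [aspects_template()].
#' @param hu named list/vector overriding tissue attenuations (`air`,
#'   `skull`, `csf`, `white`, `gray`, `deep_gray`).
#' @param noise_sd standard deviation of the additive Gaussian noise, HU.
#' @param noise_correlation_mm 0 for white noise (default); > 0 smooths the
#'   noise field at this spatial scale and rescales it back to `noise_sd`.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   phantoms.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(256L, 256L), spacing = NULL,
                           hu = list(), noise_sd = 4,
                           noise_correlation_mm = 0, seed = 1L) {
  defaults <- c(air = -1000, skull = 800, csf = 8, white = 28,
                gray = 38, deep_gray = 40)
  hu <- utils::modifyList(as.list(defaults), as.list(hu))
  bad <- setdiff(names(hu), names(defaults))
  if (length(bad)) stop(sprintf("unknown tissue(s): %s",
                                paste(bad, collapse = ", ")), call. = FALSE)
  huv <- unlist(hu)[names(defaults)]
  if (any(huv < -1024 | huv > 3071))
    stop("tissue HU must lie in [-1024, 3071]", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (noise_correlation_mm < 0)
    stop("'noise_correlation_mm' must be >= 0", call. = FALSE)
  shape <- as.integer(shape)
  if (is.null(spacing)) spacing <- 220 / shape
  structure(list(shape = shape, spacing = spacing, hu = huv,
                 noise_sd = noise_sd,
                 noise_correlation_mm = noise_correlation_mm,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Lesion specification
#'
#' An injectable hypoattenuating lesion: attenuation within (part of) one
#' ASPECTS region on one side is reduced by `delta_hu`. `coverage` is the
#' fraction of the region's pixels affected (a compact blob grown from a
#' seeded interior point); `edge_sigma_mm` feathers the lesion edge.
#'
#' @param region region name (e.g. `"lentiform"`) or code 1-10.
#' @param side `"left"` or `"right"`.
#' @param delta_hu positive HU drop inside the lesion.
#' @param coverage fraction of the region affected, in (0, 1].
#' @param edge_sigma_mm Gaussian feathering of the lesion mask edge, mm.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(region, side = c("left", "right"), delta_hu,
                        coverage = 1, edge_sigma_mm = 0) {
  side <- match.arg(side)
  code <- resolve_region(region)
  stopifnot_scalar_num(delta_hu, "delta_hu", positive = TRUE)
  if (!is.numeric(coverage) || coverage <= 0 || coverage > 1)
    stop("'coverage' must be in (0, 1]", call. = FALSE)
  if (edge_sigma_mm < 0) stop("'edge_sigma_mm' must be >= 0", call. = FALSE)
  structure(list(region = code, side = side, delta_hu = delta_hu,
                 coverage = coverage, edge_sigma_mm = edge_sigma_mm),
            class = "lesion_spec")
}

# Compact lesion mask: the round(coverage * N) region pixels nearest a
# randomly drawn interior seed pixel (RNG state supplied by the caller).
lesion_mask <- function(template, lesion) {
  lab <- template$labels
  side_mask <- if (lesion$side == "right") {
    matrix(seq_len(ncol(lab)), nrow(lab), ncol(lab), byrow = TRUE) >
      template$midline_col
  } else {
    matrix(seq_len(ncol(lab)), nrow(lab), ncol(lab), byrow = TRUE) <
      template$midline_col
  }
  m <- lab == lesion$region & side_mask
  if (!any(m))
    stop(sprintf("region '%s' not present in template",
                 region_name(lesion$region)), call. = FALSE)
  if (lesion$coverage >= 1) return(m)
  idx <- which(m, arr.ind = TRUE)
  seed_px <- idx[sample.int(nrow(idx), 1L), ]
  d2 <- (idx[, 1] - seed_px[1])^2 + (idx[, 2] - seed_px[2])^2
  keep <- order(d2)[seq_len(max(1L, round(lesion$coverage * nrow(idx))))]
  out <- matrix(FALSE, nrow(lab), ncol(lab))
  out[idx[keep, , drop = FALSE]] <- TRUE
  out
}

#' Render a synthetic brain CT slice
#'
#' Paints the template's tissue map with the configured attenuations,
#' subtracts the (optionally edge-feathered) lesion fields, and adds seeded
#' Gaussian noise. Fully deterministic given (config, lesions).
#'
#' @param config a [phantom_config()].
#' @param template an [aspects_template()] with matching shape.
#' @param lesions list of [lesion_spec()] objects (possibly empty).
#' @return A list with `slice` (a [ct_slice()]), `truth` (list with `left`
#'   and `right` integer vectors of truly lesioned region codes) and
#'   `lesions`.
#' @examples
#' tpl <- aspects_template("ganglionic", shape = c(128, 128))
#' cfg <- phantom_config(shape = c(128, 128), noise_sd = 0, seed = 1)
#' p <- render_phantom(cfg, tpl,
#'                     list(lesion_spec("lentiform", "left", delta_hu = 3)))
#' p$truth
#' @export
render_phantom <- function(config, template, lesions = list()) {
  stopifnot(inherits(config, "phantom_config"),
            inherits(template, "aspects_template"))
  if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
  if (!all(template$shape == config$shape))
    stop("template and config shapes differ", call. = FALSE)
  tiss <- template$tissue
  img <- matrix(config$hu[tiss + 1L], nrow(tiss), ncol(tiss))

  with_seed(config$seed, {
    for (les in lesions) {
      stopifnot(inherits(les, "lesion_spec"))
      m <- lesion_mask(template, les)
      field <- if (les$edge_sigma_mm > 0) {
        gaussian_lowpass(m * 1, les$edge_sigma_mm / config$spacing)
      } else m * 1
      img <- img - les$delta_hu * field
    }
    if (config$noise_sd > 0) {
      noise <- matrix(stats::rnorm(length(img), 0, config$noise_sd),
                      nrow(img), ncol(img))
      if (config$noise_correlation_mm > 0) {
        noise <- gaussian_lowpass(noise,
                                  config$noise_correlation_mm / config$spacing)
        noise <- noise * (config$noise_sd / stats::sd(as.vector(noise)))
      }
      img <- img + noise
    }
  })

  truth <- list(left = integer(0), right = integer(0))
  for (les in lesions)
    truth[[les$side]] <- sort(unique(c(truth[[les$side]], les$region)))
  list(slice = ct_slice(img, spacing = config$spacing,
                        level_tag = template$level),
       truth = truth, lesions = lesions)
}

#' Generate a cohort of phantom patients
#'
#' Emulates a stroke-imaging cohort: each patient is lesion-positive with
#' probability `prevalence`; positive patients receive 1 to `max_lesions`
#' unilateral lesions in regions drawn (without replacement) from
#' `lesion_distribution`, with per-lesion contrast and coverage drawn
#' uniformly from `delta_range` and `coverage_range`. Every patient has an
#' independent sub-seed, so the cohort is reproducible and each phantom is
#' independent of cohort order.
#'
#' The default region weights follow the spatial pattern of MCA infarcts
#' (lentiform and insula dominate); the default contrast 2-4 HU and partial
#' coverage 0.3-0.7 put the region-mean hypoattenuation near the reading
#' threshold on unprocessed images.
#'
#' @param n_patients number of phantoms.
#' @param prevalence probability a patient carries at least one lesion.
#' @param lesion_distribution named non-negative weights over region names
#'   present in the template.
#' @param seed integer master seed.
#' @param config a [phantom_config()] used as the per-patient base (its
#'   `seed` field is replaced per patient).
#' @param template an [aspects_template()]; default ganglionic at the
#'   config's shape.
#' @param delta_range,coverage_range uniform sampling ranges for lesion
#'   contrast (HU) and coverage fraction.
#' @param max_lesions maximum lesions per positive patient.
#' @param edge_sigma_mm lesion edge feathering, mm.
#' @return An object of class `ct_cohort`: a list of per-patient lists
#'   (`slice`, `truth`, `lesions`, `patient_id`, `seed`) with the template
#'   attached as attribute `template`.
#' @export
make_cohort <- function(n_patients, prevalence = 0.855,
                        lesion_distribution = c(caudate = 10, insula = 27,
                                                lentiform = 41,
                                                internal_capsule = 10,
                                                M1 = 6, M2 = 18, M3 = 4),
                        seed = 1L,
                        config = phantom_config(),
                        template = NULL,
                        delta_range = c(2, 4),
                        coverage_range = c(0.3, 0.7),
                        max_lesions = 3L,
                        edge_sigma_mm = 1) {
  if (n_patients < 1L) stop("'n_patients' must be >= 1", call. = FALSE)
  if (prevalence < 0 || prevalence > 1)
    stop("'prevalence' must be in [0, 1]", call. = FALSE)
  if (length(lesion_distribution) == 0L || all(lesion_distribution <= 0))
    stop("'lesion_distribution' must have positive weights", call. = FALSE)
  if (is.null(template))
    template <- aspects_template("ganglionic", shape = config$shape,
                                 spacing = config$spacing)
  avail <- region_name(sort(unique(template$labels[template$labels > 0])))
  lesion_distribution <- lesion_distribution[names(lesion_distribution) %in%
                                               avail]
  if (length(lesion_distribution) == 0L)
    stop("no distribution regions present in the template", call. = FALSE)

  # the master seed only fixes per-patient sub-seeds and positivity, drawn
  # as one interleaved pair per patient, so patient i is identical whatever
  # the cohort size or generation order
  meta <- with_seed(seed, {
    draws <- lapply(seq_len(n_patients), function(i)
      list(pseed = sample.int(.Machine$integer.max - 2L, 1L),
           positive = stats::runif(1) < prevalence))
    list(pseeds = vapply(draws, `[[`, 0L, "pseed"),
         positive = vapply(draws, `[[`, logical(1), "positive"))
  })
  patients <- lapply(seq_len(n_patients), function(i) {
    with_seed(meta$pseeds[i], {
      lesions <- list()
      if (meta$positive[i]) {
        side <- sample(c("left", "right"), 1L)
        k <- sample.int(min(max_lesions, length(lesion_distribution)), 1L)
        regs <- sample(names(lesion_distribution), k,
                       prob = lesion_distribution)
        lesions <- lapply(regs, function(rg)
          lesion_spec(rg, side,
                      delta_hu = stats::runif(1, delta_range[1],
                                              delta_range[2]),
                      coverage = stats::runif(1, coverage_range[1],
                                              coverage_range[2]),
                      edge_sigma_mm = edge_sigma_mm))
      }
      cfg <- config
      cfg$seed <- meta$pseeds[i] + 1L
      ph <- render_phantom(cfg, template, lesions)
      ph$patient_id <- sprintf("P%03d", i)
      ph$seed <- meta$pseeds[i]
      ph
    })
  })
  structure(patients, class = "ct_cohort", template = template,
            seed = seed, prevalence = prevalence)
}

#' @export
print.ct_cohort <- function(x, ...) {
  npos <- sum(vapply(x, function(p)
    length(p$truth$left) + length(p$truth$right) > 0, logical(1)))
  cat(sprintf("<ct_cohort> %d patients, %d lesion-positive (seed %d)\n",
              length(x), npos, attr(x, "seed")))
  invisible(x)
}
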