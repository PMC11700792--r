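#' Parameters of the synthetic CT phantom generator
#'
#' Builds the parameter set controlling phantom geometry, intensity and
#' noise. The generator draws a body disc of `body_intensity` containing two
#' darker elliptical lung fields; benign phantoms carry one small smooth
#' bright disc inside a lung field, malignant phantoms a larger lesion with
#' an irregular (spiculated) boundary and heterogeneous interior, normal
#' phantoms none. Defaults emulate the class structure of clinical 8-bit CT
#' nodule slices at desk scale.
#'
#' @param image_size pixels per side (square image), at least 32.
#' @param noise_sigma standard deviation of additive Gaussian noise, in
#'   intensity units.
#' @param benign_radius_range two-element range (pixels) for benign lesion
#'   radii.
#' @param malignant_radius_range two-element range (pixels) for malignant
#'   core radii; its minimum must not be below the benign maximum, so the
#'   classes stay geometrically separable by construction.
#' @param spiculation_count number of radial spikes on malignant lesions.
#' @param texture_roughness unitless >= 0; scales both malignant boundary
#'   irregularity and interior intensity heterogeneity.
#' @param background_lung_intensity,nodule_intensity,body_intensity grey
#'   levels in \[0, 255\] of the lung fields, the lesion and the body.
#' @param seed default seed used when none is passed to the generator.
#'
#' @return an object of class `phantom_params` (a validated list).
#' @export
phantom_params <- function(image_size = 128,
                           noise_sigma = 4,
                           benign_radius_range = c(4, 7),
                           malignant_radius_range = c(8, 14),
                           spiculation_count = 6,
                           texture_roughness = 0.5,
                           background_lung_intensity = 60,
                           nodule_intensity = 200,
                           body_intensity = 150,
                           seed = 1) {
  p <- list(image_size = as.integer(image_size),
            noise_sigma = noise_sigma,
            benign_radius_range = as.numeric(benign_radius_range),
            malignant_radius_range = as.numeric(malignant_radius_range),
            spiculation_count = as.integer(spiculation_count),
            texture_roughness = texture_roughness,
            background_lung_intensity = background_lung_intensity,
            nodule_intensity = nodule_intensity,
            body_intensity = body_intensity,
            seed = as.integer(seed))
  if (p$image_size < 32L) stopf("image_size must be >= 32, got %d", p$image_size)
  if (p$noise_sigma < 0) stopf("noise_sigma must be >= 0")
  ints <- c(p$background_lung_intensity, p$nodule_intensity, p$body_intensity)
  if (any(ints < 0 | ints > 255)) stopf("all intensity parameters must lie in [0, 255]")
  for (nm in c("benign_radius_range", "malignant_radius_range")) {
    r <- p[[nm]]
    if (length(r) != 2L || r[1] > r[2] || r[1] <= 0) stopf("%s must be an increasing positive range", nm)
  }
  if (p$malignant_radius_range[1] < p$benign_radius_range[2]) {
    stopf("malignant_radius_range minimum (%.1f) must be >= benign_radius_range maximum (%.1f)",
          p$malignant_radius_range[1], p$benign_radius_range[2])
  }
  if (p$spiculation_count < 0L) stopf("spiculation_count must be >= 0")
  if (p$texture_roughness < 0) stopf("texture_roughness must be >= 0")
  structure(p, class = "phantom_params")
}

## bilinear upsample of a small grid to nr x nc (interior heterogeneity field)
upsample_bilinear <- function(g, nr, nc) {
  gr <- nrow(g); gc <- ncol(g)
  ri <- seq(1, gr, length.out = nr)
  ci <- seq(1, gc, length.out = nc)
  r0 <- pmin(floor(ri), gr - 1L); rw <- ri - r0
  c0 <- pmin(floor(ci), gc - 1L); cw <- ci - c0
  a <- g[cbind(rep(r0, nc), rep(c0, each = nr))]
  b <- g[cbind(rep(r0 + 1, nc), rep(c0, each = nr))]
  d <- g[cbind(rep(r0, nc), rep(c0 + 1, each = nr))]
  e <- g[cbind(rep(r0 + 1, nc), rep(c0 + 1, each = nr))]
  rw <- rep(rw, nc); cw <- rep(cw, each = nr)
  matrix((1 - rw) * (1 - cw) * a + rw * (1 - cw) * b +
         (1 - rw) * cw * d + rw * cw * e, nr, nc)
}

#' Generate one synthetic lung phantom
#'
#' Deterministic given `(label, params, seed)`: calling twice with the same
#' arguments returns bit-identical images. The true lesion centre, radius
#' and pixel mask are attached to the returned sample (fields
#' `lesion_center`, `lesion_radius`, `lesion_mask`) so downstream stages can
#' be validated against ground truth.
#'
#' @param label one of `"normal"`, `"benign"`, `"malignant"`.
#' @param params a [phantom_params()] object.
#' @param seed integer seed; defaults to `params$seed`.
#' @param sample_id identifier stored on the sample.
#'
#' @return a `labeled_sample`: list with `image` (numeric matrix of integer
#'   grey levels in \[0, 255\]), `label`, `sample_id` and lesion ground truth
#'   (`NULL` for normal).
#' @export
generate_phantom <- function(label, params = phantom_params(), seed = params$seed,
                             sample_id = sprintf("%s_seed%d", label, seed)) {
  if (!is.character(label) || length(label) != 1L || !(label %in% CLASS_ORDER)) {
    stopf("unknown class label '%s' (expected one of: %s)",
          paste(label, collapse = ","), paste(CLASS_ORDER, collapse = ", "))
  }
  stopifnot(inherits(params, "phantom_params"))
  n <- params$image_size
  with_seed(seed, {
    img <- matrix(params$body_intensity, n, n)
    row <- matrix(seq_len(n), n, n)
    col <- matrix(seq_len(n), n, n, byrow = TRUE)

    ## two tall lung-field ellipses, mildly jittered per sample
    lungs <- lapply(c(0.30, 0.70), function(fx) {
      list(cx = (fx + runif(1, -0.01, 0.01)) * n,
           cy = (0.52 + runif(1, -0.01, 0.01)) * n,
           a = 0.16 * n * runif(1, 0.95, 1.05),
           b = 0.30 * n * runif(1, 0.95, 1.05))
    })
    for (L in lungs) {
      inside <- ((col - L$cx) / L$a)^2 + ((row - L$cy) / L$b)^2 <= 1
      img[inside] <- params$background_lung_intensity
    }

    lesion_center <- NULL; lesion_radius <- NULL; lesion_mask <- NULL
    if (label != "normal") {
      rng <- if (label == "benign") params$benign_radius_range else params$malignant_radius_range
      r0 <- runif(1, rng[1], rng[2])
      rough <- params$texture_roughness
      ## core boundary (incl. modulation) kept inside the lung field;
      ## malignant spikes may cross into the body
      margin <- r0 * (1 + 0.3 * rough)
      L <- lungs[[sample(2L, 1L)]]
      ar <- max(L$a - margin, 1); br <- max(L$b - margin, 1)
      th <- runif(1, 0, 2 * pi); rho <- sqrt(runif(1))
      cx <- L$cx + ar * rho * cos(th)
      cy <- L$cy + br * rho * sin(th)
      dx <- col - cx; dy <- row - cy
      d <- sqrt(dx^2 + dy^2)
      if (label == "benign") {
        lesion_mask <- d <= r0
        img[lesion_mask] <- params$nodule_intensity
      } else {
        ang <- atan2(dy, dx)
        ## smooth low-order boundary modulation, bounded at +-0.3*roughness
        amp <- runif(3) / (2:4); phs <- runif(3, 0, 2 * pi)
        smod <- function(t) {
          s <- amp[1] * cos(2 * t + phs[1]) + amp[2] * cos(3 * t + phs[2]) +
               amp[3] * cos(4 * t + phs[3])
          s / max(sum(amp), 1e-9)
        }
        rb <- r0 * (1 + 0.3 * rough * smod(ang))
        if (params$spiculation_count > 0L) {
          psi <- runif(params$spiculation_count, -pi, pi)
          for (pj in psi) {
            dth <- abs(((ang - pj + pi) %% (2 * pi)) - pi)
            rb <- rb + 0.5 * r0 * exp(-dth^2 / (2 * 0.12^2))
          }
        }
        lesion_mask <- d <= rb
        ## heterogeneous interior: smooth multiplicative noise field
        field <- upsample_bilinear(matrix(runif(36, -1, 1), 6, 6), n, n)
        lesion_int <- params$nodule_intensity * (1 + 0.35 * rough * field)
        img[lesion_mask] <- lesion_int[lesion_mask]
      }
      lesion_center <- c(row = cy, col = cx)
      lesion_radius <- r0
    }

    if (params$noise_sigma > 0) img <- img + rnorm(n * n, 0, params$noise_sigma)
    img <- round(pmin(pmax(img, 0), 255))

    structure(list(image = img, label = label, sample_id = sample_id,
                   lesion_center = lesion_center, lesion_radius = lesion_radius,
                   lesion_mask = lesion_mask),
              class = "labeled_sample")
  })
}

#' Generate a labeled phantom dataset
#'
#' Per-sample seeds are derived as `seed` plus a stable hash of
#' `(class, index)`, so adding samples of one class never reshuffles the
#' others. The default counts (52 normal / 15 benign / 70 malignant)
#' preserve, at 1/8 scale, the class imbalance of the clinical dataset the
#' generator emulates (416/120/561).
#'
#' @param counts named integer vector of per-class sample counts.
#' @param params a [phantom_params()] object.
#' @param seed base seed for the whole dataset.
#' @return list of `labeled_sample` objects.
#' @export
generate_dataset <- function(counts = c(normal = 52, benign = 15, malignant = 70),
                             params = phantom_params(), seed = params$seed) {
  if (is.null(names(counts)) || !all(names(counts) %in% CLASS_ORDER)) {
    stopf("counts must be named with classes among: %s", paste(CLASS_ORDER, collapse = ", "))
  }
  if (any(counts < 0)) stopf("per-class counts must be >= 0")
  samples <- list()
  for (cl in intersect(CLASS_ORDER, names(counts))) {
    k <- counts[[cl]]
    if (k == 0) next
    for (i in seq_len(k)) {
      sid <- sprintf("%s_%03d", cl, i)
      samples[[length(samples) + 1L]] <-
        generate_phantom(cl, params, seed = derive_seed(seed, cl, i), sample_id = sid)
    }
  }
  samples
}

#' Write a phantom dataset to disk
#'
#' Stores each image as an 8-bit grayscale PNG under one subdirectory per
#' class and writes a CSV manifest with columns `sample_id,label,path`
#' (paths relative to `directory`).
#'
#' @param samples list of `labeled_sample` objects.
#' @param directory output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(samples, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(samples, function(s) {
    stopifnot(inherits(s, "labeled_sample"))
    dir.create(file.path(directory, s$label), showWarnings = FALSE)
    rel <- file.path(s$label, paste0(s$sample_id, ".png"))
    write_image(s$image, file.path(directory, rel))
    data.frame(sample_id = s$sample_id, label = s$label, path = rel,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(directory, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a phantom dataset written by [write_dataset()]
#'
#' Image files present under the class subdirectories but absent from the
#' manifest are ignored with a warning; a manifest entry whose file is
#' missing or not 8-bit grayscale is an error naming the path.
#'
#' @param directory dataset directory containing `manifest.csv`.
#' @return list of `labeled_sample` objects (images and labels only).
#' @export
read_dataset <- function(directory) {
  mpath <- file.path(directory, "manifest.csv")
  if (!file.exists(mpath)) stopf("manifest not found: %s", mpath)
  manifest <- read.csv(mpath, stringsAsFactors = FALSE)
  need <- c("sample_id", "label", "path")
  if (!all(need %in% names(manifest))) {
    stopf("manifest %s must have columns: %s", mpath, paste(need, collapse = ","))
  }
  on_disk <- list.files(directory, pattern = "\\.png$", recursive = TRUE)
  extra <- setdiff(on_disk, manifest$path)
  if (length(extra)) {
    warning(sprintf("ignoring %d file(s) not listed in manifest: %s",
                    length(extra), paste(extra, collapse = ", ")), call. = FALSE)
  }
  lapply(seq_len(nrow(manifest)), function(i) {
    fp <- file.path(directory, manifest$path[i])
    if (!file.exists(fp)) stopf("image listed in manifest is missing: %s", fp)
    img <- read_image(fp)
    structure(list(image = img, label = manifest$label[i],
                   sample_id = manifest$sample_id[i],
                   lesion_center = NULL, lesion_radius = NULL, lesion_mask = NULL),
              class = "labeled_sample")
  })
}
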