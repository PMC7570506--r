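#' Spectral class signature
#'
#' A class's reflectance spectrum is a smooth baseline minus Gaussian
#' absorption dips (center nm, width nm as the Gaussian sigma, depth in
#' reflectance units) — the simplest functional form reproducing the NIR
#' band structure that drives these classification problems (CH2 overtone
#' near 1210 nm, OH/water bands near 1410-1450 nm). An optional texture
#' describes how a mixing field modulates this spectrum against a partner
#' spectrum across the object surface.
#'
#' @param name class name.
#' @param baseline baseline reflectance level (dimensionless).
#' @param dips list of `c(center_nm, width_nm, depth)` triples.
#' @param texture `list(type = "none")`, or
#'   `list(type = "stripes", period, orientation)` (period px, orientation
#'   degrees), `list(type = "blobs", scale)` (scale px) or
#'   `list(type = "checker", period)`.
#' @param partner optional partner `class_signature` mixed in by the
#'   texture field.
#' @return A `class_signature` object.
#' @export
class_signature <- function(name, baseline, dips = list(),
                            texture = list(type = "none"), partner = NULL) {
  structure(list(name = name, baseline = baseline, dips = dips,
                 texture = texture, partner = partner),
            class = "class_signature")
}

#' Evaluate a class signature on a wavelength grid
#' @param sig a [class_signature].
#' @param wavelengths nm vector.
#' @return Reflectance spectrum (clamped to be nonnegative).
#' @export
signature_spectrum <- function(sig, wavelengths) {
  s <- rep(sig$baseline, length(wavelengths))
  for (dp in sig$dips)
    s <- s - dp[3L] * exp(-(wavelengths - dp[1L])^2 / (2 * dp[2L]^2))
  pmax(s, 0)
}

texture_field <- function(texture, nr, nc) {
  rr <- row(matrix(0, nr, nc)); cc <- col(matrix(0, nr, nc))
  switch(texture$type,
         none = matrix(1, nr, nc),
         stripes = {
           th <- texture$orientation * pi / 180
           u <- cos(th) * rr + sin(th) * cc
           (floor(u / (texture$period / 2)) %% 2)
         },
         checker = (floor(rr / texture$period) +
                      floor(cc / texture$period)) %% 2,
         blobs = {
           z <- matrix(stats::runif(nr * nc), nr, nc)
           w <- max(1L, as.integer(texture$scale))
           zs <- z
           for (pass in 1:2) {
             zs <- t(apply(zs, 1L, function(v)
               stats::filter(v, rep(1 / w, w), circular = TRUE)))
             zs <- apply(zs, 2L, function(v)
               stats::filter(v, rep(1 / w, w), circular = TRUE))
           }
           (zs > stats::median(zs)) * 1
         },
         stop("unknown texture type: ", texture$type))
}

# smooth low-frequency field in [0, 1] emulating surface thickness drift
thickness_field <- function(nr, nc) {
  rr <- row(matrix(0, nr, nc)) / nr; cc <- col(matrix(0, nr, nc)) / nc
  f <- 0
  for (i in 1:2)
    f <- f + stats::runif(1, 0.5, 1.5) *
      cos(2 * pi * (stats::runif(1, 0.5, 1.2) * rr +
                    stats::runif(1, 0.5, 1.2) * cc) + stats::runif(1, 0, 2 * pi))
  (f - min(f)) / max(f - min(f), 1e-12)
}

# ---- object shapes (sweets) --------------------------------------------

shape_mask <- function(kind, nr, nc, cy, cx, scale) {
  rr <- row(matrix(0, nr, nc)); cc <- col(matrix(0, nr, nc))
  switch(kind,
         ellipse = ((rr - cy) / (0.95 * scale))^2 +
                   ((cc - cx) / (1.3 * scale))^2 <= 1,
         mushroom = {
           cap <- (((rr - cy + 0.3 * scale) / (0.7 * scale))^2 +
                     ((cc - cx) / (1.2 * scale))^2 <= 1) & (rr <= cy)
           stem <- abs(cc - cx) <= 0.35 * scale &
             rr > cy & rr <= cy + 1.1 * scale
           cap | stem
         },
         teeth = {
           body <- abs(rr - cy) <= 0.7 * scale & abs(cc - cx) <= 1.2 * scale
           notches <- rr > cy + 0.15 * scale &
             (floor((cc - cx + 1.2 * scale) / (0.45 * scale)) %% 2 == 1)
           body & !notches
         },
         bottle = {
           body <- rr >= cy - 0.2 * scale & rr <= cy + 1.1 * scale &
             abs(cc - cx) <= 0.8 * scale
           neck <- rr < cy - 0.2 * scale & rr >= cy - 1.1 * scale &
             abs(cc - cx) <= 0.35 * scale
           body | neck
         },
         stop("unknown shape: ", kind))
}

# ---- scenario configurations -------------------------------------------

#' Scenario configuration: four sweet products
#'
#' 101 bands over 943-1643 nm (7 nm spacing). Four classes with distinct
#' baselines, absorption-band structure and object shapes; no texture
#' (each object is spectrally homogeneous), which makes the classes
#' separable in the spectral domain as well as the spatial one. The white
#' support tile is spectrally flat, so the 957/1496 nm band difference
#' isolates the sample.
#'
#' @param image_size c(rows, cols) of each scene.
#' @param noise_sd per-band Gaussian noise sd (reflectance units).
#' @param scatter_range per-pixel multiplicative scatter range.
#' @param offset_range per-pixel additive offset range.
#' @param specular_fraction fraction of foreground pixels clipped to 1.2.
#' @return A `scene_config`.
#' @export
sweets_config <- function(image_size = c(32L, 32L), noise_sd = 0.01,
                          scatter_range = c(0.93, 1.07),
                          offset_range = c(-0.03, 0.03),
                          specular_fraction = 0) {
  sigs <- list(
    class_signature("RFM", 0.80,
                    list(c(1190, 35, 0.10), c(1450, 55, 0.45))),
    class_signature("Mint", 0.60,
                    list(c(1210, 40, 0.20), c(1460, 55, 0.38))),
    class_signature("Teeth", 0.75,
                    list(c(1195, 35, 0.12), c(1450, 55, 0.42))),
    class_signature("Tub", 0.45,
                    list(c(1410, 60, 0.18), c(1460, 50, 0.30))))
  structure(list(scenario = "sweets",
                 wavelengths = seq(943, 1643, by = 7),
                 image_size = as.integer(image_size),
                 signatures = sigs,
                 shapes = c("mushroom", "ellipse", "teeth", "bottle"),
                 background = class_signature("tile", 0.92),
                 noise_sd = noise_sd,
                 scatter_range = scatter_range,
                 offset_range = offset_range,
                 interference_amp_range = c(0, 0),
                 specular_fraction = specular_fraction),
            class = "scene_config")
}

#' Scenario configuration: salmon fillet tissue
#'
#' 180 bands over 900-1700 nm. Two interleaved tissue classes — thin
#' bright connective-tissue stripes (myocommata) between wider red-muscle
#' blocks (myotome) — in a slanted zebra pattern on an elliptical fillet.
#' Each scene adds a smooth per-scene baseline interference (surface
#' thickness / batch effect): a random low-frequency thickness field times
#' a broad interference spectrum, with a per-scene amplitude drawn from
#' `interference_amp_range`. A small fraction of specular pixels is
#' clipped near saturation. The interference dominates the between-class
#' spectral contrast, which is what makes orthogonalizing it worthwhile.
#'
#' @param image_size c(rows, cols).
#' @param stripe_period,stripe_width zebra geometry in px (stripe =
#'   myocommata width within each period).
#' @param interference_amp_range per-scene amplitude range of the baseline
#'   interference (reflectance units) for training and validation fillets.
#' @param interference_amp_range_test amplitude range for test fillets,
#'   emulating fillets from different batches whose thickness interference
#'   exceeds what the training batches showed.
#' @inheritParams sweets_config
#' @return A `scene_config`.
#' @export
salmon_config <- function(image_size = c(32L, 32L), noise_sd = 0.035,
                          scatter_range = c(0.95, 1.05),
                          offset_range = c(-0.02, 0.02),
                          interference_amp_range = c(0.05, 0.2),
                          interference_amp_range_test = c(0.2, 0.35),
                          specular_fraction = 0.01,
                          stripe_period = 7L, stripe_width = 2L) {
  # the two tissues differ by a brightness offset (which the thickness
  # interference confounds) and a weak CH2-band-shape residue at 1210 nm
  # (which it does not)
  sigs <- list(
    class_signature("myocommata", 0.66,
                    list(c(1210, 35, 0.07), c(1450, 55, 0.30))),
    class_signature("myotome", 0.52,
                    list(c(1210, 35, 0.11), c(1450, 55, 0.28))))
  structure(list(scenario = "salmon",
                 wavelengths = seq(900, 1700, length.out = 180),
                 image_size = as.integer(image_size),
                 signatures = sigs,
                 stripe_period = as.integer(stripe_period),
                 stripe_width = as.integer(stripe_width),
                 background = class_signature("stage", 0.10),
                 noise_sd = noise_sd,
                 scatter_range = scatter_range,
                 offset_range = offset_range,
                 interference_amp_range = interference_amp_range,
                 interference_amp_range_test = interference_amp_range_test,
                 specular_fraction = specular_fraction),
            class = "scene_config")
}

#' Spatial-only variant of the sweets scenario
#'
#' The adversarial case separating spectral-only from spectral-spatial
#' classifiers: every class shares one spectral signature pair and differs
#' only through its binary texture (stripe orientation / checker), each
#' with a 50% duty cycle and the same object shape. The per-pixel marginal
#' spectral distribution is therefore identical across classes — a purely
#' spectral classifier can do no better than chance — while any classifier
#' that sees the spatial neighborhood can read the texture.
#'
#' @param config a sweets `scene_config`.
#' @return A modified `scene_config`.
#' @export
spatial_only_variant <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  if (config$scenario != "sweets")
    stop("the spatial-only variant is defined for the sweets scenario")
  a <- class_signature("shared_a", 0.75,
                       list(c(1200, 40, 0.12), c(1450, 55, 0.42)))
  b <- class_signature("shared_b", 0.75,
                       list(c(1200, 40, 0.32), c(1450, 55, 0.42)))
  tex <- list(list(type = "stripes", period = 8, orientation = 0),
              list(type = "stripes", period = 8, orientation = 90),
              list(type = "stripes", period = 8, orientation = 45),
              list(type = "checker", period = 4))
  config$signatures <- lapply(seq_along(tex), function(i) {
    s <- a
    s$name <- paste0("texture", i)
    s$texture <- tex[[i]]
    s$partner <- b
    s
  })
  config$shapes <- rep("ellipse", 4L)
  config$spatial_only <- TRUE
  config
}

# render the spectra of a set of pixels: base mixed signature, scatter,
# offset, interference, noise
render_pixels <- function(config, sigsA, sigsB, mix, n_bands, intf) {
  npx <- nrow(sigsA)
  stopifnot(ncol(sigsA) == n_bands)
  base <- sigsA * mix + sigsB * (1 - mix)
  a <- stats::runif(npx, config$scatter_range[1L], config$scatter_range[2L])
  b <- stats::runif(npx, config$offset_range[1L], config$offset_range[2L])
  out <- base * a + b + intf +
    matrix(stats::rnorm(npx * n_bands, 0, config$noise_sd), npx, n_bands)
  pmin(pmax(out, 0), 1.3)
}

#' Render one synthetic scene
#'
#' Deterministic given `seed`. Every foreground pixel's spectrum is its
#' class signature (possibly texture-mixed with a partner spectrum) times a
#' per-pixel multiplicative scatter, plus a per-pixel offset, the
#' per-scene interference times the local thickness, and i.i.d. Gaussian
#' noise; specular pixels are overwritten with near-saturation values
#' (clipped at 1.2). The returned label image is the exact ground truth,
#' and the cube's mask is the true foreground.
#'
#' @param config a `scene_config`.
#' @param content for the sweets scenario: a class index (single-object
#'   scene) or `"mixed"` (two objects of every class); ignored for salmon
#'   scenes, which always contain both tissue classes.
#' @param seed scene seed (mandatory).
#' @param amp_range override of the per-scene interference amplitude range
#'   (used by [generate_dataset()] for test fillets from other batches).
#' @return List with `cube` (a masked, labelled [hypercube]) and `truth`
#'   (a [label_image]).
#' @export
render_scene <- function(config, content = 1L, seed, amp_range = NULL) {
  stopifnot(inherits(config, "scene_config"))
  if (missing(seed)) stop("`seed` is mandatory")
  set.seed(seed)
  wl <- config$wavelengths
  nb <- length(wl)
  nr <- config$image_size[1L]; nc <- config$image_size[2L]
  class_names <- vapply(config$signatures, `[[`, character(1L), "name")
  lab <- matrix(0L, nr, nc)
  mix <- matrix(1, nr, nc)

  if (config$scenario == "salmon") {
    scale <- 0.42 * min(nr, nc)
    fg <- shape_mask("ellipse", nr, nc,
                     nr / 2 + stats::runif(1, -1, 1),
                     nc / 2 + stats::runif(1, -1, 1), scale)
    slant <- stats::runif(1, 0.15, 0.45)
    phase <- sample.int(config$stripe_period, 1L)
    u <- (col(lab) + round(slant * row(lab)) + phase) %% config$stripe_period
    lab[fg] <- ifelse(u[fg] < config$stripe_width, 1L, 2L)
    scene_label <- "salmon"
  } else if (identical(content, "mixed")) {
    # two objects of every class on a coarse grid; mixed scenes are rendered
    # at twice the configured size so the objects keep their single-scene scale
    nr <- 2L * nr; nc <- 2L * nc
    lab <- matrix(0L, nr, nc); mix <- matrix(1, nr, nc)
    cells <- expand.grid(r = seq_len(3L), c = seq_len(3L))
    cells <- cells[sample.int(nrow(cells), 8L), ]
    order_cls <- rep(seq_along(config$signatures), 2L)
    scale <- 0.11 * min(nr, nc)
    for (i in seq_len(8L)) {
      cy <- (cells$r[i] - 0.5) * nr / 3 + stats::runif(1, -1, 1)
      cx <- (cells$c[i] - 0.5) * nc / 3 + stats::runif(1, -1, 1)
      cls <- order_cls[i]
      m <- shape_mask(config$shapes[cls], nr, nc, cy, cx, scale)
      lab[m & lab == 0L] <- cls
    }
    scene_label <- "mixed"
  } else {
    cls <- as.integer(content)
    scale <- stats::runif(1, 0.3, 0.36) * min(nr, nc)
    cy <- nr / 2 + stats::runif(1, -1.5, 1.5)
    cx <- nc / 2 + stats::runif(1, -1.5, 1.5)
    m <- shape_mask(config$shapes[cls], nr, nc, cy, cx, scale)
    lab[m] <- cls
    scene_label <- class_names[cls]
  }
  if (!any(lab > 0L)) stop("rendered scene has no foreground")

  # per-class texture mixing fields
  for (cls in sort(unique(lab[lab > 0L]))) {
    tex <- config$signatures[[cls]]$texture
    if (!identical(tex$type, "none")) {
      tf <- texture_field(tex, nr, nc)
      mix[lab == cls] <- tf[lab == cls]
    }
  }

  # per-scene interference: a smooth baseline whose slope and curvature are
  # scene-specific (thickness and batch effects do not repeat across fillets)
  if (is.null(amp_range)) amp_range <- config$interference_amp_range
  amp <- stats::runif(1, amp_range[1L], amp_range[2L])
  tnorm <- (wl - min(wl)) / (max(wl) - min(wl)) - 0.5
  intf_spec <- 1 + 0.3 * tnorm
  thick <- thickness_field(nr, nc)

  data <- array(0, c(nr, nc, nb))
  flat <- matrix(0, nr * nc, nb)
  spectra <- t(vapply(config$signatures, signature_spectrum,
                      numeric(nb), wavelengths = wl))
  partnerA <- spectra
  partnerB <- spectra
  for (cls in seq_along(config$signatures)) {
    pt <- config$signatures[[cls]]$partner
    if (!is.null(pt)) partnerB[cls, ] <- signature_spectrum(pt, wl)
  }
  fg_idx <- which(lab > 0L)
  clsv <- lab[fg_idx]
  intf_px <- amp * thick[fg_idx]
  flat[fg_idx, ] <- render_pixels(config,
                                  partnerA[clsv, , drop = FALSE],
                                  partnerB[clsv, , drop = FALSE],
                                  mix[fg_idx],
                                  nb,
                                  outer(intf_px, intf_spec))
  bg_idx <- which(lab == 0L)
  if (length(bg_idx)) {
    bg_spec <- signature_spectrum(config$background, wl)
    flat[bg_idx, ] <- render_pixels(config,
                                    matrix(bg_spec, length(bg_idx), nb,
                                           byrow = TRUE),
                                    matrix(bg_spec, length(bg_idx), nb,
                                           byrow = TRUE),
                                    rep(1, length(bg_idx)), nb, 0)
  }
  if (config$specular_fraction > 0) {
    nspec <- round(config$specular_fraction * length(fg_idx))
    if (nspec > 0L) {
      sp <- sample(fg_idx, nspec)
      flat[sp, ] <- 1.2
    }
  }
  data[] <- flat  # (pixel, band) linear order matches (row, col, band)
  cube <- hypercube(data, wl, mask = lab > 0L, label = scene_label)
  list(cube = cube, truth = label_image(lab, class_names))
}

#' Generate a full train/validation/test dataset of synthetic scenes
#'
#' Scene-level splits are disjoint by construction (every scene is rendered
#' from its own seed). For the sweets scenario, `n_train` and `n_val`
#' count single-class scenes per class; test scenes are mixed-composition
#' images when `mixed_test = TRUE` (each then contains at least two
#' classes), otherwise one more single-class scene per class. For the
#' salmon scenario the counts are whole-fillet scenes, each containing
#' both tissue classes.
#'
#' @param config a `scene_config`.
#' @param n_train,n_val,n_test split sizes (see above).
#' @param mixed_test sweets only: render test scenes as mixtures.
#' @param seed master seed; per-scene seeds are derived from it.
#' @return List with `train`, `val`, `test` (lists of
#'   `list(cube, truth, seed)`), `class_names` and `manifest` (a data frame
#'   with split, scene seed and per-class pixel counts).
#' @export
generate_dataset <- function(config, n_train = 3L, n_val = 1L, n_test = 2L,
                             mixed_test = FALSE, seed) {
  stopifnot(inherits(config, "scene_config"))
  if (missing(seed)) stop("`seed` is mandatory")
  if (n_train < 1L || n_val < 1L || n_test < 0L) stop("invalid split sizes")
  class_names <- vapply(config$signatures, `[[`, character(1L), "name")
  C <- length(class_names)
  sweets <- config$scenario == "sweets"
  plan <- list()
  if (sweets) {
    for (cls in seq_len(C)) {
      plan <- c(plan,
                lapply(seq_len(n_train), function(i) list(split = "train", content = cls)),
                lapply(seq_len(n_val), function(i) list(split = "val", content = cls)))
    }
    if (n_test > 0L) {
      tc <- if (mixed_test) "mixed" else NULL
      for (i in seq_len(n_test)) {
        if (mixed_test) {
          plan <- c(plan, list(list(split = "test", content = "mixed")))
        } else {
          for (cls in seq_len(C))
            plan <- c(plan, list(list(split = "test", content = cls)))
        }
      }
    }
  } else {
    mkp <- function(split, k) lapply(seq_len(k), function(i)
      list(split = split, content = 1L))
    plan <- c(mkp("train", n_train), mkp("val", n_val), mkp("test", n_test))
  }
  set.seed(seed)
  scene_seeds <- sample.int(.Machine$integer.max - 1L, length(plan))
  out <- list(train = list(), val = list(), test = list())
  rows <- list()
  for (i in seq_along(plan)) {
    ar <- NULL
    if (!sweets && plan[[i]]$split == "test")
      ar <- config$interference_amp_range_test
    sc <- render_scene(config, content = plan[[i]]$content,
                       seed = scene_seeds[i], amp_range = ar)
    sc$seed <- scene_seeds[i]
    out[[plan[[i]]$split]] <- c(out[[plan[[i]]$split]], list(sc))
    cnt <- vapply(seq_len(C), function(k) sum(sc$truth$labels == k), integer(1L))
    rows[[i]] <- data.frame(scene = i, split = plan[[i]]$split,
                            seed = scene_seeds[i],
                            content = as.character(plan[[i]]$content),
                            t(stats::setNames(cnt, class_names)))
  }
  out$class_names <- class_names
  out$manifest <- do.call(rbind, rows)
  out
}
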