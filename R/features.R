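#' Feature-stack configuration
#'
#' Controls the hand-crafted per-pixel features fed to the pixel classifiers.
#' Scales form a geometric sigma ladder doubling from `min_sigma` up to (and
#' including) `max_sigma`; the defaults 1.0 and 16.0 give the ladder
#' 1, 2, 4, 8, 16. Membrane projections use rotated line kernels of length
#' `membrane_patch_size` and width `membrane_thickness`.
#'
#' @param min_sigma,max_sigma Smallest and largest filter scale (px).
#' @param membrane_thickness Width of the membrane line kernels (px).
#' @param membrane_patch_size Side of the membrane kernel patch; odd, >= 3.
#' @param families Ordered character vector of feature family names; see
#'   [feature_families()] for the registry. Defaults to the basic set used
#'   with the random-forest classifier.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(min_sigma = 1.0, max_sigma = 16.0,
                           membrane_thickness = 1L, membrane_patch_size = 19L,
                           families = default_families("random_forest")) {
  if (!(min_sigma > 0 && min_sigma <= max_sigma))
    stop("need 0 < min_sigma <= max_sigma")
  membrane_patch_size <- as.integer(membrane_patch_size)
  if (membrane_patch_size < 3L || membrane_patch_size %% 2L == 0L)
    stop("membrane_patch_size must be odd and >= 3")
  families <- as.character(families)
  bad <- setdiff(families, feature_families())
  if (length(bad))
    stop("unknown feature family name(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(families)) stop("duplicated feature family names")
  structure(list(min_sigma = min_sigma, max_sigma = max_sigma,
                 membrane_thickness = as.integer(membrane_thickness),
                 membrane_patch_size = membrane_patch_size,
                 families = families),
            class = "feature_config")
}

#' Registry of implemented feature families
#'
#' The basic set (`gaussian`, `sobel`, `hessian`, `dog`, `membrane`) is the
#' default for the random-forest classifier; the extended set adds the rank,
#' texture and edge-preserving filters used with the Bayesian classifier.
#'
#' @return Character vector of valid family names.
#' @export
feature_families <- function() {
  c("gaussian", "sobel", "hessian", "dog", "membrane",
    "variance", "mean", "minimum", "maximum", "median",
    "anisotropic_diffusion", "bilateral", "lipschitz", "kuwahara",
    "gabor", "entropy", "neighbors")
}

#' @rdname feature_families
#' @param model_type `"random_forest"` or `"bayes"`.
#' @export
default_families <- function(model_type = c("random_forest", "bayes")) {
  model_type <- match.arg(model_type)
  basic <- c("gaussian", "sobel", "hessian", "dog", "membrane")
  if (model_type == "random_forest") basic else c(basic, setdiff(feature_families(), basic))
}

#' Sigma ladder of filter scales
#'
#' Doubles from `min_sigma` up to and including `max_sigma`, stopping before
#' exceeding it: the default 1.0..16.0 yields 1, 2, 4, 8, 16.
#'
#' @param config A [feature_config] (or anything with `min_sigma`/`max_sigma`).
#' @return Numeric vector of sigmas.
#' @export
sigma_ladder <- function(config) {
  s <- config$min_sigma
  out <- numeric()
  while (s <= config$max_sigma + 1e-12) {
    out <- c(out, s)
    s <- s * 2
  }
  out
}

# ---- convolution with reflect padding --------------------------------------

# Mirror-pad a matrix by (pr, pc); pad must be <= dim - 1.
pad_reflect <- function(x, pr, pc) {
  nr <- nrow(x); nc <- ncol(x)
  if (pr > nr - 1L || pc > nc - 1L)
    stop("image too small for reflect padding of ", pr, "x", pc)
  ri <- c(rev(seq_len(pr) + 1L), seq_len(nr), nr - seq_len(pr))
  ci <- c(rev(seq_len(pc) + 1L), seq_len(nc), nc - seq_len(pc))
  x[ri, ci, drop = FALSE]
}

# 2D correlation with reflect border handling; kernel dims must be odd.
conv2_reflect <- function(x, kernel, family = "filter") {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  if (kr > nrow(x) - 1L || kc > ncol(x) - 1L)
    stop("image (", nrow(x), "x", ncol(x), ") smaller than the '", family,
         "' kernel (", nrow(kernel), "x", ncol(kernel), ")")
  xp <- pad_reflect(x, kr, kc)
  y <- EBImage::filter2(xp, kernel, boundary = "replicate")
  y[(kr + 1L):(kr + nrow(x)), (kc + 1L):(kc + ncol(x)), drop = FALSE]
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_kernel <- function(sigma) {
  k1 <- gaussian_kernel_1d(sigma)
  outer(k1, k1)
}

gauss_smooth <- function(x, sigma, family = "gaussian") {
  conv2_reflect(x, gaussian_kernel(sigma), family = family)
}

# Central-difference derivative planes of a smoothed image.
deriv_x <- function(x) conv2_reflect(x, matrix(c(-0.5, 0, 0.5), 1, 3))
deriv_y <- function(x) conv2_reflect(x, matrix(c(-0.5, 0, 0.5), 3, 1))

disk_kernel <- function(radius) {
  r <- max(1L, as.integer(round(radius)))
  d <- outer((-r:r)^2, (-r:r)^2, `+`) <= r^2
  k <- matrix(0, 2L * r + 1L, 2L * r + 1L)
  k[d] <- 1
  k
}

# ---- feature families ------------------------------------------------------

membrane_kernels <- function(patch_size, thickness, n_angles = 30L) {
  half <- (patch_size - 1) / 2
  idx <- seq(-half, half)
  lapply(seq_len(n_angles) - 1L, function(a) {
    th <- a * pi / n_angles             # 6 degree steps for 30 rotations
    ux <- cos(th); uy <- sin(th)
    # distance of each patch cell to the line through the centre
    X <- matrix(rep(idx, each = patch_size), patch_size)   # column offsets
    Y <- matrix(rep(idx, times = patch_size), patch_size)  # row offsets
    along <- X * ux + Y * uy
    across <- abs(-X * uy + Y * ux)
    k <- (across <= thickness / 2 + 1e-9) & (abs(along) <= half + 1e-9)
    k <- k * 1
    k / sum(k)                          # mean along the line
  })
}

#' Membrane projection features
#'
#' Convolves the image with 30 rotated line kernels (length
#' `patch_size`, width `thickness`, 6 degree steps) and aggregates the
#' responses across rotations per pixel with sum, mean, standard deviation,
#' median, maximum and minimum, giving six feature planes that respond to
#' elongated (membrane-like) structures regardless of orientation. Each line
#' kernel is normalized to sum 1, so all six planes reduce to the image value
#' (and the sd plane to 0) on locally constant data.
#'
#' @param image Numeric matrix (already normalized to \[0, 1\]).
#' @param thickness Line width in pixels.
#' @param patch_size Odd kernel side length.
#' @return Named list of six matrices: `sum`, `mean`, `sd`, `median`,
#'   `max`, `min`.
#' @export
membrane_projections <- function(image, thickness = 1L, patch_size = 19L) {
  if (patch_size %% 2L == 0L) stop("membrane patch_size must be odd")
  ks <- membrane_kernels(patch_size, thickness)
  planes <- lapply(ks, function(k) conv2_reflect(image, k, family = "membrane"))
  arr <- array(unlist(planes), dim = c(nrow(image), ncol(image), length(planes)))
  agg <- function(f) apply(arr, c(1, 2), f)
  n <- length(planes)
  s <- Reduce(`+`, planes)
  m <- s / n
  v <- Reduce(`+`, lapply(planes, function(p) p^2)) / n - m^2
  list(sum = s,
       mean = m,
       sd = sqrt(pmax(v, 0)),
       median = agg(stats::median),
       max = Reduce(pmax, planes),
       min = Reduce(pmin, planes))
}

local_mean <- function(x, radius) {
  k <- disk_kernel(radius)
  conv2_reflect(x, k / sum(k), family = "mean")
}

local_variance <- function(x, radius) {
  m <- local_mean(x, radius)
  m2 <- local_mean(x * x, radius)
  pmax(m2 - m^2, 0)
}

local_entropy <- function(x, radius, n_bins = 64L) {
  b <- pmin(floor(x * n_bins) + 1L, n_bins)
  k <- disk_kernel(radius); k <- k / sum(k)
  h <- matrix(0, nrow(x), ncol(x))
  for (bin in sort(unique(as.vector(b)))) {
    p <- conv2_reflect((b == bin) * 1, k, family = "entropy")
    nz <- p > 1e-12
    h[nz] <- h[nz] - p[nz] * log2(p[nz])
  }
  h
}

shift_reflect <- function(x, dr, dc) {
  p <- max(abs(dr), abs(dc))
  if (p == 0L) return(x)
  xp <- pad_reflect(x, p, p)
  xp[(p + 1L + dr):(p + nrow(x) + dr), (p + 1L + dc):(p + ncol(x) + dc),
     drop = FALSE]
}

gabor_kernel <- function(theta, wavelength, sigma = 0.56 * wavelength,
                         gamma = 0.5) {
  r <- as.integer(ceiling(2.5 * sigma))
  idx <- seq(-r, r)
  X <- matrix(rep(idx, each = length(idx)), length(idx))
  Y <- matrix(rep(idx, times = length(idx)), length(idx))
  xr <- X * cos(theta) + Y * sin(theta)
  yr <- -X * sin(theta) + Y * cos(theta)
  env <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2))
  k <- env * cos(2 * pi * xr / wavelength)
  k - mean(k)                            # zero-DC so flat regions give 0
}

kuwahara_filter <- function(x, radius = 2L) {
  # 4 overlapping quadrant windows of side radius+1; output = mean of the
  # quadrant with the smallest variance
  r <- radius
  box <- matrix(1 / (r + 1)^2, r + 1L, r + 1L)
  offs <- list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  best_m <- matrix(0, nrow(x), ncol(x))
  best_v <- matrix(Inf, nrow(x), ncol(x))
  half <- r %/% 2L + r %% 2L   # shift of each quadrant centre
  for (o in offs) {
    xs <- shift_reflect(x, o[1] * half, o[2] * half)
    m <- conv2_reflect(xs, box, family = "kuwahara")
    v <- conv2_reflect(xs * xs, box, family = "kuwahara") - m^2
    upd <- v < best_v
    best_m[upd] <- m[upd]
    best_v[upd] <- v[upd]
  }
  best_m
}

bilateral_filter <- function(x, radius = 2L, sigma_s = 2, sigma_r = 0.1) {
  num <- matrix(0, nrow(x), ncol(x))
  den <- matrix(0, nrow(x), ncol(x))
  for (dr in -radius:radius) for (dc in -radius:radius) {
    xs <- shift_reflect(x, dr, dc)
    w <- exp(-(dr^2 + dc^2) / (2 * sigma_s^2)) *
      exp(-(xs - x)^2 / (2 * sigma_r^2))
    num <- num + w * xs
    den <- den + w
  }
  num / den
}

anisotropic_diffusion_filter <- function(x, n_iter = 10L, kappa = 0.1,
                                         lambda = 0.2) {
  u <- x
  for (i in seq_len(n_iter)) {
    dn <- shift_reflect(u, -1L, 0L) - u
    ds <- shift_reflect(u, 1L, 0L) - u
    de <- shift_reflect(u, 0L, 1L) - u
    dw <- shift_reflect(u, 0L, -1L) - u
    g <- function(d) exp(-(d / kappa)^2)
    u <- u + lambda * (g(dn) * dn + g(ds) * ds + g(de) * de + g(dw) * dw)
  }
  u
}

lipschitz_filter <- function(x, slope = 0.04) {
  # top-hat against the lower Lipschitz cover: raster passes pull the cover
  # down to at most neighbour + slope, forward then backward until stable
  l <- x
  nr <- nrow(x); nc <- ncol(x)
  for (pass in 1:2) {
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      up <- if (i > 1L) l[i - 1L, j] + slope else Inf
      lf <- if (j > 1L) l[i, j - 1L] + slope else Inf
      l[i, j] <- min(l[i, j], up, lf)
    }
    for (i in rev(seq_len(nr))) for (j in rev(seq_len(nc))) {
      dn <- if (i < nr) l[i + 1L, j] + slope else Inf
      rt <- if (j < nc) l[i, j + 1L] + slope else Inf
      l[i, j] <- min(l[i, j], dn, rt)
    }
  }
  x - l
}

# Normalize intensities to [0,1]: full bit-depth scale when known, otherwise
# leave [0,1] data alone and divide anything else by its maximum.
normalize_intensity <- function(image) {
  if (inherits(image, "image_plane")) {
    px <- image$pixels
    if (!is.null(image$bit_depth)) return(px / (2^image$bit_depth - 1))
    image <- px
  }
  image <- as.matrix(image)
  mx <- max(image)
  if (mx <= 1) image else image / mx
}

#' Build the per-pixel feature stack
#'
#' Computes every feature family requested in `config` on the intensity image
#' (internally rescaled to \[0, 1\]) and stacks them as a height x width x
#' n_features array. Feature names and order are fully determined by the
#' configuration, so stacks built on different images are always column
#' compatible. Border handling is reflect padding throughout.
#'
#' Family definitions (per sigma of the ladder unless noted): `gaussian` =
#' isotropic Gaussian blur; `sobel` = gradient magnitude of the blurred
#' image; `hessian` = both Hessian eigenvalues plus the Frobenius norm (3
#' planes); `dog` = all ordered ladder pairs G(s_i) - G(s_j), s_i < s_j;
#' `membrane` = the six [membrane_projections] aggregations (ladder
#' independent); `variance`/`mean`/`minimum`/`maximum`/`median` = disk rank
#' filters of radius sigma; `entropy` = local Shannon entropy (64-bin) in a
#' disk of radius sigma; `neighbors` = the 8 reflect-shifted copies at offset
#' sigma; `gabor` = a 4 orientation x 2 wavelength quadrature-free Gabor
#' bank (8 planes, ladder independent); `kuwahara`, `bilateral`,
#' `anisotropic_diffusion`, `lipschitz` = one plane each at fixed standard
#' parameters.
#'
#' @param image An [image_plane] or numeric matrix.
#' @param config A [feature_config].
#' @return A `feature_stack`: 3D array with `dimnames[[3]]` the feature names
#'   and attribute `feature_config`.
#' @export
build_feature_stack <- function(image, config = feature_config()) {
  x <- normalize_intensity(image)
  sig <- sigma_ladder(config)
  planes <- list()
  smooth_cache <- new.env(parent = emptyenv())
  smoothed <- function(s) {
    key <- format(s)
    if (is.null(smooth_cache[[key]]))
      smooth_cache[[key]] <- gauss_smooth(x, s)
    smooth_cache[[key]]
  }
  for (fam in config$families) {
    switch(fam,
      gaussian = for (s in sig)
        planes[[sprintf("gaussian_s%g", s)]] <- smoothed(s),
      sobel = for (s in sig) {
        g <- smoothed(s)
        planes[[sprintf("sobel_s%g", s)]] <- sqrt(deriv_x(g)^2 + deriv_y(g)^2)
      },
      hessian = for (s in sig) {
        g <- smoothed(s)
        dxx <- deriv_x(deriv_x(g)); dyy <- deriv_y(deriv_y(g))
        dxy <- deriv_y(deriv_x(g))
        tr <- dxx + dyy
        disc <- sqrt(pmax((dxx - dyy)^2 + 4 * dxy^2, 0))
        planes[[sprintf("hessian_eig1_s%g", s)]] <- (tr + disc) / 2
        planes[[sprintf("hessian_eig2_s%g", s)]] <- (tr - disc) / 2
        planes[[sprintf("hessian_frob_s%g", s)]] <-
          sqrt(dxx^2 + 2 * dxy^2 + dyy^2)
      },
      dog = {
        if (length(sig) > 1L) {
          for (i in seq_len(length(sig) - 1L)) for (j in (i + 1L):length(sig))
            planes[[sprintf("dog_s%g_s%g", sig[i], sig[j])]] <-
              smoothed(sig[i]) - smoothed(sig[j])
        }
      },
      membrane = {
        mp <- membrane_projections(x, config$membrane_thickness,
                                   config$membrane_patch_size)
        for (nm in names(mp)) planes[[paste0("membrane_", nm)]] <- mp[[nm]]
      },
      variance = for (s in sig)
        planes[[sprintf("variance_s%g", s)]] <- local_variance(x, s),
      mean = for (s in sig)
        planes[[sprintf("mean_s%g", s)]] <- local_mean(x, s),
      minimum = for (s in sig)
        planes[[sprintf("minimum_s%g", s)]] <-
          as.matrix(EBImage::erode(x, disk_kernel(s))),
      maximum = for (s in sig)
        planes[[sprintf("maximum_s%g", s)]] <-
          as.matrix(EBImage::dilate(x, disk_kernel(s))),
      median = for (s in sig)
        planes[[sprintf("median_s%g", s)]] <-
          as.matrix(EBImage::medianFilter(pmin(pmax(x, 0), 1),
                                          max(1L, as.integer(round(s))))),
      entropy = for (s in sig)
        planes[[sprintf("entropy_s%g", s)]] <- local_entropy(x, s),
      neighbors = for (s in sig) {
        o <- max(1L, as.integer(round(s)))
        dirs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                     c(0, 1), c(1, -1), c(1, 0), c(1, 1))
        for (d in seq_along(dirs))
          planes[[sprintf("neighbors_s%g_d%d", s, d)]] <-
            shift_reflect(x, dirs[[d]][1] * o, dirs[[d]][2] * o)
      },
      gabor = {
        for (th in 0:3) for (wl in c(4, 8))
          planes[[sprintf("gabor_o%d_w%g", th * 45L, wl)]] <-
            conv2_reflect(x, gabor_kernel(th * pi / 4, wl), family = "gabor")
      },
      kuwahara = planes[["kuwahara"]] <- kuwahara_filter(x),
      bilateral = planes[["bilateral"]] <- bilateral_filter(x),
      anisotropic_diffusion =
        planes[["anisotropic_diffusion"]] <- anisotropic_diffusion_filter(x),
      lipschitz = planes[["lipschitz"]] <- lipschitz_filter(x),
      stop("unknown feature family: ", fam)
    )
  }
  stack <- array(unlist(planes, use.names = FALSE),
                 dim = c(nrow(x), ncol(x), length(planes)),
                 dimnames = list(NULL, NULL, names(planes)))
  if (any(!is.finite(stack))) stop("non-finite feature values produced")
  structure(stack, feature_config = config,
            class = c("feature_stack", "array"))
}

#' Names of the features a configuration produces
#'
#' Reproducible from the configuration alone (no image needed): used to check
#' classifier/stack compatibility.
#'
#' @param config A [feature_config].
#' @return Character vector of feature names in stack order.
#' @export
feature_names <- function(config) {
  sig <- sigma_ladder(config)
  out <- character()
  for (fam in config$families) {
    out <- c(out, switch(fam,
      gaussian = sprintf("gaussian_s%g", sig),
      sobel = sprintf("sobel_s%g", sig),
      hessian = as.vector(outer(c("hessian_eig1_s%g", "hessian_eig2_s%g",
                                  "hessian_frob_s%g"), sig, sprintf)),
      dog = if (length(sig) > 1L) {
        prs <- utils::combn(sig, 2)
        sprintf("dog_s%g_s%g", prs[1, ], prs[2, ])
      } else character(),
      membrane = paste0("membrane_", c("sum", "mean", "sd", "median",
                                       "max", "min")),
      variance = sprintf("variance_s%g", sig),
      mean = sprintf("mean_s%g", sig),
      minimum = sprintf("minimum_s%g", sig),
      maximum = sprintf("maximum_s%g", sig),
      median = sprintf("median_s%g", sig),
      entropy = sprintf("entropy_s%g", sig),
      neighbors = as.vector(t(outer(sig, 1:8,
                                    function(s, d) sprintf("neighbors_s%g_d%d", s, d)))),
      gabor = as.vector(t(outer(c(0L, 45L, 90L, 135L), c(4, 8),
                                function(o, w) sprintf("gabor_o%d_w%g", o, w)))),
      kuwahara = "kuwahara",
      bilateral = "bilateral",
      anisotropic_diffusion = "anisotropic_diffusion",
      lipschitz = "lipschitz"))
  }
  out
}
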