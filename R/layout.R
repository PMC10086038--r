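#' Build a planar-gradiometer sensor layout
#'
#' Constructs a helmet-plane layout of combined-gradiometer sites. Sites are
#' placed on a unit disc with a sunflower (golden-angle) pattern plus a small
#' seeded jitter; with \code{symmetric = TRUE} the layout is exactly
#' mirror-symmetric about the vertical midline x = 0 (a midline column takes
#' any odd remainder). Each site carries two gradiometer channels
#' (\code{<site>_g1}, \code{<site>_g2}). The default 102 sites mirror the
#' combined-gradiometer count of a 306-channel Vectorview-style system.
#'
#' @param nSites number of combined-gradiometer sites (>= 2).
#' @param symmetric logical; build a mirror-symmetric layout.
#' @param seed integer seed for the positional jitter (layout is fully
#'   deterministic given the seed).
#' @param neighborRadius spatial neighbourhood radius in layout units;
#'   default \code{sqrt(7.5 / nSites)} gives about six neighbours per site
#'   on the default layout.
#' @return a [SensorLayout-class]
#' @examples
#' lay <- makeLayout(nSites = 10, seed = 1)
#' siteTable(lay)
#' @export
makeLayout <- function(nSites = 102L, symmetric = TRUE, seed = 1L,
                       neighborRadius = NULL) {
  if (nSites < 2L) stop("nSites must be at least 2", call. = FALSE)
  nSites <- as.integer(nSites)
  if (is.null(neighborRadius)) neighborRadius <- sqrt(7.5 / nSites)
  set.seed(as.integer(seed))
  golden <- pi * (3 - sqrt(5))
  if (symmetric) {
    nMid <- nSites %% 2L
    nHalf <- nSites %/% 2L
    i <- seq_len(nHalf)
    r <- sqrt((i - 0.5) / nHalf)
    # golden-angle fractions folded into the right half-plane
    a <- (i * golden) %% pi - pi / 2
    xr <- 0.08 + 0.92 * r * cos(a)          # keep strictly right of midline
    yr <- r * sin(a)
    jit <- stats::rnorm(nHalf, 0, 0.02)
    yr <- yr + jit                          # shared by mirrored partners
    x <- c(-xr, xr, rep(0, nMid))
    y <- c(yr, yr, if (nMid) 0.9 else NULL)
  } else {
    i <- seq_len(nSites)
    r <- sqrt((i - 0.5) / nSites)
    a <- i * golden
    x <- r * cos(a) + stats::rnorm(nSites, 0, 0.02)
    y <- r * sin(a) + stats::rnorm(nSites, 0, 0.02)
  }
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  site <- sprintf("S%03d", seq_len(nSites))
  hemi <- ifelse(x < 0, "left", ifelse(x > 0, "right", "midline"))
  region <- ifelse(y < -0.4, "occipital",
            ifelse(y < 0, "parietal",
            ifelse(y < 0.45, "central", "frontal")))
  sites <- data.frame(site = site, x = x, y = y, hemisphere = hemi,
                      region = region, stringsAsFactors = FALSE)
  pairs <- data.frame(site = site,
                      ch1 = paste0(site, "_g1"),
                      ch2 = paste0(site, "_g2"),
                      stringsAsFactors = FALSE)
  methods::new("SensorLayout", sites = sites, pairs = pairs,
               neighborRadius = neighborRadius)
}

#' Spatial adjacency from a layout
#'
#' Two sites are neighbours when their helmet-plane distance is strictly
#' smaller than the layout's \code{neighborRadius}. The result is symmetric
#' with no self-edges.
#'
#' @param layout a [SensorLayout-class]
#' @param radius optional override of the layout's neighbour radius
#' @return logical sites x sites matrix (dimnames = site ids)
#' @export
adjacencyFromLayout <- function(layout, radius = NULL) {
  stopifnot(methods::is(layout, "SensorLayout"))
  if (is.null(radius)) radius <- layout@neighborRadius
  s <- layout@sites
  d <- as.matrix(stats::dist(cbind(s$x, s$y)))
  adj <- d < radius
  diag(adj) <- FALSE
  dimnames(adj) <- list(s$site, s$site)
  adj
}

#' @describeIn makeLayout site table accessor
#' @param object a \code{SensorLayout}
#' @export
setMethod("siteTable", "SensorLayout", function(object, ...) object@sites)

#' @describeIn makeLayout gradiometer pair table accessor
#' @export
setMethod("channelPairs", "SensorLayout", function(object, ...) object@pairs)

#' @describeIn makeLayout number of sites
#' @export
setMethod("nSites", "SensorLayout", function(object, ...) nrow(object@sites))

setMethod("show", "SensorLayout", function(object) {
  s <- object@sites
  cat(sprintf("SensorLayout: %d sites (%d left / %d right / %d midline), %d gradiometer channels\n",
              nrow(s), sum(s$hemisphere == "left"),
              sum(s$hemisphere == "right"), sum(s$hemisphere == "midline"),
              2L * nrow(s)))
  cat(sprintf("  neighborRadius: %.3f\n", object@neighborRadius))
})

#' Write/read a layout as JSON
#'
#' @param layout a [SensorLayout-class]
#' @param path file path
#' @return \code{writeLayoutJson}: the path, invisibly;
#'   \code{readLayoutJson}: a [SensorLayout-class]
#' @export
writeLayoutJson <- function(layout, path) {
  obj <- list(sites = layout@sites, pairs = layout@pairs,
              neighborRadius = layout@neighborRadius)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname writeLayoutJson
#' @export
readLayoutJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("SensorLayout",
               sites = as.data.frame(obj$sites, stringsAsFactors = FALSE),
               pairs = as.data.frame(obj$pairs, stringsAsFactors = FALSE),
               neighborRadius = as.numeric(obj$neighborRadius))
}
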