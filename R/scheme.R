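#' Construct a landmark scheme
#'
#' @param nTotal total number of points per configuration.
#' @param fixedIndices integer indices (1-based) of the fixed landmarks.
#' @param semiCurves list of ordered integer vectors, one per curve; the
#'   first and last entry of each curve are fixed-landmark anchors, the
#'   interior entries are the sliding semi-landmarks.
#' @param curveNames optional character names for the curves.
#' @return a [LandmarkScheme-class].
#' @examples
#' LandmarkScheme(5L, c(1L, 2L, 5L), list(c(1L, 3L, 4L, 5L)), "arc")
#' @export
LandmarkScheme <- function(nTotal, fixedIndices, semiCurves = list(),
                           curveNames = NULL) {
  if (is.null(curveNames))
    curveNames <- if (length(semiCurves)) paste0("curve", seq_along(semiCurves))
                  else character(0)
  new("LandmarkScheme", nTotal = as.integer(nTotal),
      fixedIndices = as.integer(sort(fixedIndices)),
      semiCurves = lapply(semiCurves, as.integer),
      curveNames = as.character(curveNames))
}

#' Read / write a landmark scheme configuration file
#'
#' Schemes are stored as editable YAML (or JSON) with fields `n_total`,
#' `fixed_indices` and `semi_curves` (a named list of ordered index
#' vectors, 1-based, anchors included at both ends).
#'
#' @param path file path (.yaml/.yml or .json).
#' @return [LandmarkScheme-class] (for the reader); `writeLandmarkScheme`
#'   returns `path` invisibly.
#' @export
readLandmarkScheme <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  LandmarkScheme(cfg$n_total, unlist(cfg$fixed_indices),
                 lapply(cfg$semi_curves, unlist),
                 curveNames = names(cfg$semi_curves))
}

#' @rdname readLandmarkScheme
#' @param scheme a [LandmarkScheme-class].
#' @export
writeLandmarkScheme <- function(scheme, path) {
  cfg <- list(n_total = scheme@nTotal,
              fixed_indices = scheme@fixedIndices,
              semi_curves = stats::setNames(scheme@semiCurves,
                                            scheme@curveNames))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE)
  else yaml::write_yaml(cfg, path)
  invisible(path)
}

#' The packaged 70-point facial landmark scheme
#'
#' A frontal-face scheme of 70 points: 36 fixed landmarks placed at
#' classical anthropometric positions (eyes, brows' ends, nose, mouth,
#' chin, jaw angles, zygions, one forehead point, two upper facial-outline
#' anchors) and 34 sliding semi-landmarks on three curves: the facial
#' outline (20 points) and the left and right eyebrows (7 points each).
#' The exact curve membership lives in an editable configuration file
#' (`inst/extdata/face70_scheme.yaml`); this scheme reproduces the point
#' counts and curve topology of the classical frontal scheme, not the
#' anatomical definitions of any particular digitizing protocol.
#'
#' @return a [LandmarkScheme-class] with 70 points.
#' @examples
#' defaultLandmarkScheme()
#' @export
defaultLandmarkScheme <- function() {
  path <- system.file("extdata", "face70_scheme.yaml", package = "FaceTrust")
  if (nzchar(path)) return(readLandmarkScheme(path))
  # fallback when called from a source tree
  LandmarkScheme(70L, 1:36,
                 list(outline = c(35L, 37:56, 36L),
                      brow_left = c(15L, 57:63, 16L),
                      brow_right = c(17L, 64:70, 18L)),
                 curveNames = c("outline", "brow_left", "brow_right"))
}

# Fixed-landmark layout of the schematic template face, up-positive y,
# roughly 2 units tall. Outline anchors (35, 36) sit exactly on the
# outline ellipse so the curve is smooth through them.
.templateFixed <- function() {
  ell <- function(theta) c(0.70 * cos(theta), -0.05 + 0.95 * sin(theta))
  deg <- pi / 180
  m <- rbind(
    forehead        = c( 0.00,  0.95),
    nasion          = c( 0.00,  0.50),
    pronasale       = c( 0.00,  0.05),
    subnasale       = c( 0.00, -0.05),
    alare_L         = c(-0.15,  0.00),
    alare_R         = c( 0.15,  0.00),
    endocanthion_L  = c(-0.15,  0.35),
    exocanthion_L   = c(-0.45,  0.35),
    palp_sup_L      = c(-0.30,  0.42),
    palp_inf_L      = c(-0.30,  0.28),
    endocanthion_R  = c( 0.15,  0.35),
    exocanthion_R   = c( 0.45,  0.35),
    palp_sup_R      = c( 0.30,  0.42),
    palp_inf_R      = c( 0.30,  0.28),
    brow_inner_L    = c(-0.12,  0.55),
    brow_outer_L    = c(-0.50,  0.52),
    brow_inner_R    = c( 0.12,  0.55),
    brow_outer_R    = c( 0.50,  0.52),
    cheilion_L      = c(-0.25, -0.35),
    cheilion_R      = c( 0.25, -0.35),
    labiale_sup     = c( 0.00, -0.28),
    labiale_inf     = c( 0.00, -0.45),
    stomion         = c( 0.00, -0.36),
    crista_phil_L   = c(-0.08, -0.30),
    crista_phil_R   = c( 0.08, -0.30),
    sublabiale      = c( 0.00, -0.58),
    pogonion        = c( 0.00, -0.80),
    gnathion        = c( 0.00, -0.97),
    gonion_L        = c(-0.55, -0.45),
    gonion_R        = c( 0.55, -0.45),
    zygion_L        = c(-0.65,  0.15),
    zygion_R        = c( 0.65,  0.15),
    infraorb_L      = c(-0.30,  0.18),
    infraorb_R      = c( 0.30,  0.18),
    outline_anc_L   = ell(160 * deg),
    outline_anc_R   = ell(20 * deg))
  m
}

#' The schematic 70-point template face
#'
#' Coordinates (70 x 2, up-positive y) of a symmetric, sexually
#' undifferentiated schematic frontal face consistent with
#' [defaultLandmarkScheme()]. Used as the base configuration of the face
#' simulator; it is a synthetic stand-in, not an empirical mean face.
#'
#' @return numeric matrix 70 x 2 with point names.
#' @examples
#' tpl <- faceTemplate(); dim(tpl)
#' @export
faceTemplate <- function() {
  fixed <- .templateFixed()
  deg <- pi / 180
  # outline semi-landmarks: ellipse arc from the left anchor (160 deg)
  # through the chin (270 deg) to the right anchor (380 deg)
  th <- (160 + 220 * (1:20) / 21) * deg
  outline <- cbind(0.70 * cos(th), -0.05 + 0.95 * sin(th))
  rownames(outline) <- paste0("outline_s", 1:20)
  # eyebrow semi-landmarks: quadratic Bezier between the brow anchors
  bez <- function(p0, pc, p1, t)
    cbind((1 - t)^2 %o% p0[1] + 2 * t * (1 - t) %o% pc[1] + t^2 %o% p1[1],
          (1 - t)^2 %o% p0[2] + 2 * t * (1 - t) %o% pc[2] + t^2 %o% p1[2])
  t7 <- (1:7) / 8
  browL <- bez(fixed["brow_inner_L", ], c(-0.31, 0.64),
               fixed["brow_outer_L", ], t7)
  browR <- bez(fixed["brow_inner_R", ], c(0.31, 0.64),
               fixed["brow_outer_R", ], t7)
  rownames(browL) <- paste0("browL_s", 1:7)
  rownames(browR) <- paste0("browR_s", 1:7)
  out <- rbind(fixed, outline, browL, browR)
  dimnames(out)[[2]] <- c("x", "y")
  out
}

#' The packaged dimorphism displacement field
#'
#' A unit-norm per-point displacement field over the template face encoding
#' the qualitative male-female shape contrast reported for European faces:
#' relative to females, males have a longer, wider and more robust lower
#' face and jaw, thinner lips, lower and more medially set eyebrows,
#' smaller visible eye areas, and a bilaterally asymmetric component
#' deforming the left side of the face. Adding \code{+delta/2} times this
#' field produces a male-directed shape, \code{-delta/2} a female-directed
#' one, so \code{delta} is the full male-female mean difference in template
#' units. Hand-authored qualitative emulation, not a reconstruction of any
#' empirical sample.
#'
#' @return numeric matrix 70 x 2 with unit Frobenius norm.
#' @examples
#' sum(dimorphismField()^2)  # 1
#' @export
dimorphismField <- function() {
  tpl <- faceTemplate()
  d <- matrix(0, nrow(tpl), 2, dimnames = dimnames(tpl))
  nm <- rownames(tpl)
  lower <- tpl[, 2] < -0.35 & abs(tpl[, 1]) > 0.01
  jawpts <- nm %in% c("gonion_L", "gonion_R") |
    (grepl("^outline_s", nm) & lower)
  # male: wider, longer, more robust jaw and lower face
  d[jawpts, 1] <- d[jawpts, 1] + 0.55 * sign(tpl[jawpts, 1])
  d[jawpts, 2] <- d[jawpts, 2] - 0.35
  mid <- nm %in% c("gnathion", "pogonion", "sublabiale")
  d[mid, 2] <- d[mid, 2] - 0.55
  # male: thinner lips (midline lip points converge on the stomion)
  d["labiale_sup", 2] <- -0.45
  d["labiale_inf", 2] <- 0.45
  d[c("crista_phil_L", "crista_phil_R"), 2] <- -0.30
  # male: lower, more medially set brows
  brow <- grepl("^brow", nm)
  d[brow, 2] <- d[brow, 2] - 0.40
  d[brow, 1] <- d[brow, 1] - 0.18 * sign(tpl[brow, 1])
  # male: smaller visible eye area
  d[c("palp_sup_L", "palp_sup_R"), 2] <- -0.22
  d[c("palp_inf_L", "palp_inf_R"), 2] <- 0.22
  # male: bilateral asymmetry deforming the left side of the face
  leftjaw <- (grepl("^outline_s", nm) | nm == "gonion_L") &
    tpl[, 1] < -0.05 & tpl[, 2] < 0.2
  d[leftjaw, 1] <- d[leftjaw, 1] - 0.25
  d[leftjaw, 2] <- d[leftjaw, 2] - 0.12
  d / sqrt(sum(d^2))
}
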