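#' Coarse-grained B-form geometry of the prism
#'
#' The closed prism is modelled as two parallel equilateral triangles
#' (side = 21 bp, one face per triangle) joined by three vertical 10-bp
#' struts, using the canonical B-DNA rise of 0.34 nm per base pair. The
#' two backbone nicks (dye and quencher attachment points) sit at the
#' midpoints of the second side of each face, offset radially outward by
#' the helix radius.
#'
#' @param rise_per_bp Helical rise (nm/bp).
#' @param strut_bp Vertical edge length (bp).
#' @param side_bp Face side length (bp).
#' @param helix_radius Radial offset of backbone points from the helix
#'   axis (nm).
#' @param face_twist Relative rotation of the two faces (degrees; 0 =
#'   eclipsed faces).
#' @return An object of class `geometry_params`.
#' @export
geometry_params <- function(rise_per_bp = 0.34, strut_bp = 10, side_bp = 21,
                            helix_radius = 1.0, face_twist = 0) {
  p <- list(rise_per_bp = rise_per_bp, strut_bp = strut_bp,
            side_bp = side_bp, helix_radius = helix_radius,
            face_twist = face_twist)
  pos <- c("rise_per_bp", "strut_bp", "side_bp", "helix_radius")
  bad <- pos[!vapply(p[pos], function(x)
    is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, logical(1))]
  if (length(bad) > 0) {
    stop("geometry parameter error: non-positive ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(p, class = "geometry_params")
}

#' Derived lengths of the prism geometry
#'
#' @param p A [geometry_params()] object.
#' @return Named list: `strut_nm` (vertical edge), `side_nm` (face side),
#'   `volume_nm3` (interior volume `sqrt(3)/4 * side^2 * height`).
#' @examples
#' prism_dimensions(geometry_params())  # 3.40 nm, 7.14 nm, ~75 nm^3
#' @export
prism_dimensions <- function(p = geometry_params()) {
  stopifnot(inherits(p, "geometry_params"))
  side <- p$rise_per_bp * p$side_bp
  strut <- p$rise_per_bp * p$strut_bp
  list(strut_nm = strut, side_nm = side,
       volume_nm3 = sqrt(3) / 4 * side^2 * strut)
}

#' Vertex and nick coordinates of the closed prism
#'
#' @param p A [geometry_params()] object.
#' @return A tibble of labelled 3-D points (nm): six triangle vertices
#'   (`A1`-`A3` at z = 0, `B1`-`B3` at z = strut) and the two nick points
#'   (`nickA`, `nickB`) at the midpoints of the second side of each face,
#'   offset radially by the helix radius.
#' @export
build_geometry <- function(p = geometry_params()) {
  stopifnot(inherits(p, "geometry_params"))
  dims <- prism_dimensions(p)
  side <- dims$side_nm
  rc <- side / sqrt(3)                    # circumradius of the face
  angles_a <- pi / 2 + c(0, 2, 4) * pi / 3
  angles_b <- angles_a + p$face_twist * pi / 180
  vert <- function(angles, z, labels) {
    tibble::tibble(point = labels,
                   x = rc * cos(angles), y = rc * sin(angles), z = z)
  }
  va <- vert(angles_a, 0, paste0("A", 1:3))
  vb <- vert(angles_b, dims$strut_nm, paste0("B", 1:3))
  # nick at the midpoint of the side joining vertices 2 and 3 of each
  # face, pushed radially outward by the helix radius
  nick <- function(v, label) {
    mid <- c(mean(v$x[2:3]), mean(v$y[2:3]))
    r <- sqrt(sum(mid^2))
    out <- if (r > 0) mid / r * (r + p$helix_radius) else mid
    tibble::tibble(point = label, x = out[1], y = out[2], z = v$z[1])
  }
  dplyr::bind_rows(va, vb, nick(va, "nickA"), nick(vb, "nickB"))
}

#' FRET efficiency at a given dye-quencher distance
#'
#' Point-dipole Foerster transfer: `E = 1 / (1 + (r/R0)^6)`, strictly
#' decreasing in `r`, with `E = 1/2` at the Foerster radius.
#'
#' @param r Dye-quencher distance (nm); `Inf` gives 0.
#' @param R0 Foerster radius (nm).
#' @return Transfer efficiency in `[0, 1]`.
#' @examples
#' fret_efficiency(5.99, 5.99)  # 0.5 by definition
#' @export
fret_efficiency <- function(r, R0) {
  if (any(r < 0)) stop("distance r must be non-negative", call. = FALSE)
  if (any(R0 <= 0)) stop("R0 must be positive", call. = FALSE)
  ifelse(is.infinite(r), 0, 1 / (1 + (r / R0)^6))
}

#' Invert the Foerster equation
#'
#' Exact inverse of [fret_efficiency()]: `r = R0 * ((1 - E) / E)^(1/6)`.
#'
#' @param E Transfer efficiency, strictly inside `(0, 1)`.
#' @param R0 Foerster radius (nm).
#' @return Distance `r` (nm).
#' @export
invert_fret <- function(E, R0) {
  if (any(E <= 0 | E >= 1)) {
    stop("efficiency must lie strictly within (0, 1)", call. = FALSE)
  }
  if (any(R0 <= 0)) stop("R0 must be positive", call. = FALSE)
  R0 * ((1 - E) / E)^(1 / 6)
}

#' Fluorescence signal model of the prism states
#'
#' Maps each structural state to a dye-quencher distance and thence,
#' through the Foerster equation, to a normalized fluorescence intensity
#' (NFI; the fully unquenched dye defines 1.0). The Foerster radius is
#' calibrated as `r_closed / 0.6^(1/6)` (about 5.99 nm, within the
#' literature range for a ROX/BHQ-2 pair) so that the closed prism
#' fluoresces at exactly 37.5% of the unquenched intensity at the 5.5-nm
#' closed-state distance - the two printed quantities are mutually
#' consistent by construction. Binary gate read-out thresholds the NFI at
#' 0.6.
#'
#' @param r_closed Closed-prism dye-quencher distance (nm).
#' @param r_monoC3 Distance after displacement of edge 3 only, which
#'   leaves the relative dye/quencher position nearly unchanged (nm).
#' @param r_opened_lid Distance once a dye- or quencher-adjacent edge has
#'   opened a lid (nm; floppy, so a single effective value is used).
#' @param threshold NFI decision threshold of the binary decoder.
#' @param R0 Foerster radius (nm); default calibrated from `r_closed` and
#'   the closed-state residual fluorescence.
#' @param nfi_closed Residual fluorescence fraction of the closed prism
#'   used for the calibration.
#' @return An object of class `signal_model`.
#' @examples
#' m <- signal_model()
#' round(m$R0, 2)  # 5.99
#' @export
signal_model <- function(r_closed = 5.5, r_monoC3 = 5.8, r_opened_lid = 12.0,
                         threshold = 0.6, R0 = NULL, nfi_closed = 0.375) {
  stopifnot(r_closed > 0, r_closed <= r_monoC3, r_monoC3 < r_opened_lid,
            threshold > 0, threshold < 1,
            nfi_closed > 0, nfi_closed < 1)
  # Calibration: 1 - E(r_closed) = nfi_closed  =>  (r/R0)^6 = nfi/(1-nfi)
  if (is.null(R0)) {
    R0 <- r_closed / (nfi_closed / (1 - nfi_closed))^(1 / 6)
  }
  stopifnot(R0 > 0)
  m <- list(r_closed = r_closed, r_monoC3 = r_monoC3,
            r_opened_lid = r_opened_lid, threshold = threshold, R0 = R0)
  structure(m, class = "signal_model")
}

#' Normalized fluorescence intensity of a prism state
#'
#' Looks up the state's effective dye-quencher distance (closed;
#' mono-SD(C3); any lid-opened mono-/di-SD state; dissociated tri-SD at
#' infinite separation) and returns `1 - E`.
#'
#' @param state A [prism_state()] object or a canonical state label.
#' @param model A [signal_model()].
#' @return NFI in `[0, 1]`.
#' @export
nfi <- function(state, model = signal_model()) {
  label <- if (inherits(state, "prism_state")) state$label else state
  r <- state_distance(label, model)
  1 - fret_efficiency(r, model$R0)
}

state_distance <- function(label, model) {
  if (label == "closed") return(model$r_closed)
  if (label == "mono-SD(C3)") return(model$r_monoC3)
  if (grepl("^mono-SD\\(C[12]\\)$", label)) return(model$r_opened_lid)
  if (grepl("^di-SD\\(C[123]/C[123]\\)$", label)) return(model$r_opened_lid)
  if (label == "tri-SD(C1/C2/C3)") return(Inf)
  stop("classification error: unknown state label '", label, "'",
       call. = FALSE)
}

#' @export
print.signal_model <- function(x, ...) {
  cat(sprintf(
    "<signal_model> R0 %.3f nm; r(closed) %.2f, r(mono-C3) %.2f, r(lid) %.2f nm; threshold NFI %.2f\n",
    x$R0, x$r_closed, x$r_monoC3, x$r_opened_lid, x$threshold))
  invisible(x)
}

#' Write prism coordinates as an xyz file
#'
#' Plain-text xyz records (label, x, y, z in nm) for visualization.
#'
#' @param geometry A tibble from [build_geometry()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(geometry, path) {
  lines <- c(as.character(nrow(geometry)), "prism geometry (nm)",
             sprintf("%-6s %10.4f %10.4f %10.4f", geometry$point,
                     geometry$x, geometry$y, geometry$z))
  writeLines(lines, path)
  invisible(path)
}
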