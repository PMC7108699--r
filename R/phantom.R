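.phantomCache <- new.env(parent = emptyenv())

# logical containment mask of points (n x 3 matrix) in one primitive row
.containedIn <- function(row, pts) {
  dx <- pts[, 1] - row$cx
  dy <- pts[, 2] - row$cy
  dz <- pts[, 3] - row$cz
  switch(row$primitive,
    sphere = dx^2 + dy^2 + dz^2 <= row$d1^2,
    cylinder = dx^2 + dy^2 <= row$d1^2 & abs(dz) <= row$d2,
    ellipsoid = (dx / row$d1)^2 + (dy / row$d2)^2 + (dz / row$d3)^2 <= 1,
    box = abs(dx) <= row$d1 & abs(dy) <= row$d2 & abs(dz) <= row$d3,
    stop("unknown primitive: ", row$primitive))
}

#' Index of the phantom entry containing each point
#'
#' Entries are tested in phantom order; the first containing primitive
#' wins (earlier entries shadow later ones), 0 means ambient air.
#'
#' @param phantom a \linkS4class{PhantomGeometry}.
#' @param pts numeric matrix n x 3 of coordinates, cm.
#' @return integer vector of entry indices (0 = outside all primitives).
#' @export
phantomEntryAt <- function(phantom, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  o <- phantom@organs
  idx <- integer(nrow(pts))
  open <- seq_len(nrow(pts))
  for (i in seq_len(nrow(o))) {
    if (!length(open)) break
    hit <- .containedIn(o[i, ], pts[open, , drop = FALSE])
    idx[open[hit]] <- i
    open <- open[!hit]
  }
  idx
}

# bounding box of a primitive row: rbind(lo, hi)
.primitiveBox <- function(row) {
  c0 <- c(row$cx, row$cy, row$cz)
  half <- switch(row$primitive,
    sphere = rep(row$d1, 3),
    cylinder = c(row$d1, row$d1, row$d2),
    ellipsoid = c(row$d1, row$d2, row$d3),
    box = c(row$d1, row$d2, row$d3))
  rbind(c0 - half, c0 + half)
}

#' Load a phantom geometry
#'
#' Reads a YAML phantom description (see the bundled
#' \code{phantom_head_neck.yaml} for the format) and derives per-entry
#' masses by grid integration of the shadowed geometry at resolution
#' \code{gridCm}, times the material bulk density. The bundled phantom is
#' cached after the first load.
#'
#' @param path YAML file, or \code{NULL} for the bundled stylized
#'   head-and-neck phantom.
#' @param gridCm integration grid spacing for mass derivation, cm.
#' @return a \linkS4class{PhantomGeometry}.
#' @export
loadPhantom <- function(path = NULL, gridCm = 0.25) {
  if (is.null(path)) path <- cbctdoseFile("phantom_head_neck.yaml")
  key <- paste(normalizePath(path), gridCm)
  if (!is.null(.phantomCache[[key]])) return(.phantomCache[[key]])
  doc <- yaml::read_yaml(path)
  if (is.null(doc$organs)) stop("phantom file needs an 'organs' list")
  organs <- do.call(rbind, lapply(doc$organs, function(o) {
    dims <- as.numeric(unlist(o$dims))
    dims <- c(dims, rep(NA_real_, 3 - length(dims)))
    data.frame(id = o$id, organ = o$organ, primitive = o$primitive,
               material = o$material,
               cx = o$center[[1]], cy = o$center[[2]], cz = o$center[[3]],
               d1 = dims[1], d2 = dims[2], d3 = dims[3],
               mass_g = NA_real_)
  }))
  boxes <- lapply(seq_len(nrow(organs)), function(i)
    .primitiveBox(organs[i, ]))
  lo <- do.call(pmin, lapply(boxes, function(b) b[1, ]))
  hi <- do.call(pmax, lapply(boxes, function(b) b[2, ]))
  center <- (lo + hi) / 2
  radius <- sqrt(sum(((hi - lo) / 2)^2)) + 0.5
  # shadow-aware volumes by midpoint-grid integration
  gx <- seq(lo[1] + gridCm / 2, hi[1], by = gridCm)
  gy <- seq(lo[2] + gridCm / 2, hi[2], by = gridCm)
  gz <- seq(lo[3] + gridCm / 2, hi[3], by = gridCm)
  pts <- as.matrix(expand.grid(gx, gy, gz))
  tmp <- new("PhantomGeometry", organs = transform(organs, mass_g = 1),
             referencePoint = as.numeric(unlist(
               doc$reference_point %||% c(0, 0, 0))),
             boundCenter = center, boundRadius = radius)
  counts <- tabulate(phantomEntryAt(tmp, pts), nbins = nrow(organs))
  dens <- vapply(organs$material, function(m) .matPar(m)$density,
                 numeric(1))
  organs$mass_g <- counts * gridCm^3 * dens
  if (any(organs$mass_g <= 0))
    stop("phantom entry with zero integrated volume: ",
         paste(organs$id[organs$mass_g <= 0], collapse = ", "))
  ph <- new("PhantomGeometry", organs = organs,
            referencePoint = tmp@referencePoint,
            boundCenter = center, boundRadius = radius)
  validObject(ph)
  .phantomCache[[key]] <- ph
  ph
}

#' Organ groups of a phantom
#'
#' Entries sharing an organ label (paired organs such as the eyes) form one
#' tally group; masses add.
#'
#' @param phantom a \linkS4class{PhantomGeometry}.
#' @return data.frame with columns \code{organ}, \code{mass_g}.
#' @export
phantomOrganMasses <- function(phantom) {
  m <- tapply(phantom@organs$mass_g, phantom@organs$organ, sum)
  data.frame(organ = names(m), mass_g = as.numeric(m),
             row.names = NULL)
}

setMethod("show", "PhantomGeometry", function(object) {
  cat(sprintf(
    "PhantomGeometry: %d primitives, %d organ groups, total mass %.0f g\n",
    nrow(object@organs), length(unique(object@organs$organ)),
    sum(object@organs$mass_g)))
  cat(sprintf("  reference point (%.1f, %.1f, %.1f) cm, bounding radius %.1f cm\n",
              object@referencePoint[1], object@referencePoint[2],
              object@referencePoint[3], object@boundRadius))
})
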