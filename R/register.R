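#' Landmark set for rigid head registration
#'
#' @param points n x 3 matrix of coordinates (mm).
#' @param names landmark names; defaults to the eight anatomical
#'   references used for neuronavigation calibration (inion, right outer
#'   eye corner, nasion, left/right preauricular, glabella, left/right
#'   alar).
#' @return object of class `landmark_set` (data frame name, x, y, z).
#' @export
landmark_set <- function(points, names = NULL) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (is.null(names)) {
    default <- c("inion", "right_eye_corner", "nasion",
                 "preauricular_left", "preauricular_right",
                 "glabella", "left_alar", "right_alar")
    names <- if (nrow(points) == 8) default else
      paste0("p", seq_len(nrow(points)))
  }
  if (anyDuplicated(names)) stop("landmark names must be unique")
  structure(data.frame(name = names, x = points[, 1], y = points[, 2],
                       z = points[, 3], stringsAsFactors = FALSE),
            class = c("landmark_set", "data.frame"))
}

as_points <- function(x) {
  if (inherits(x, "landmark_set")) as.matrix(x[, c("x", "y", "z")])
  else matrix(as.numeric(x), ncol = 3)
}

#' Least-squares rigid registration of paired landmarks
#'
#' Estimates the rotation and translation aligning source landmarks to
#' destination landmarks by the SVD (Kabsch) solution of the orthogonal
#' Procrustes problem, with the determinant-corrected rotation so that
#' reflections are excluded.  Reports the fiducial registration error
#' (FRE): the RMS residual distance over landmark pairs.
#'
#' @param src,dst `landmark_set`s or n x 3 matrices with matched rows
#'   (>= 3 non-collinear points).
#' @return object of class `rigid_transform`: `rotation` (3 x 3),
#'   `translation` (length 3), `fre` (mm).
#' @export
fit_rigid <- function(src, dst) {
  if (inherits(src, "landmark_set") && inherits(dst, "landmark_set")) {
    if (!identical(src$name, dst$name)) stop("landmark names do not match")
  }
  P <- as_points(src); Q <- as_points(dst)
  if (nrow(P) != nrow(Q)) stop("point counts differ")
  if (nrow(P) < 3) stop("need at least 3 landmark pairs")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (qr(Pc)$rank < 2) stop("degenerate (collinear) landmark configuration")
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- unname(cq - drop(R %*% cp))
  res <- Q - (P %*% t(R) + matrix(t, nrow(P), 3, byrow = TRUE))
  fre <- sqrt(mean(rowSums(res^2)))
  structure(list(rotation = R, translation = t, fre = fre),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param transform a `rigid_transform`.
#' @param points n x 3 matrix or `landmark_set`.
#' @return transformed points, same shape/class as the input coordinates.
#' @export
apply_transform <- function(transform, points) {
  P <- as_points(points)
  out <- P %*% t(transform$rotation) +
    matrix(transform$translation, nrow(P), 3, byrow = TRUE)
  if (inherits(points, "landmark_set")) {
    points[, c("x", "y", "z")] <- out
    points
  } else out
}

#' @export
print.rigid_transform <- function(x, ...) {
  m <- rbind(cbind(x$rotation, x$translation), c(0, 0, 0, 1))
  cat("Rigid transform (homogeneous 4x4), FRE =",
      format(x$fre, digits = 4), "mm\n")
  print(round(m, 6))
  invisible(x)
}

#' Check guided optode placement against saved positions
#'
#' An optode is "on position" when it lies within `tol` mm of its saved
#' location, mirroring the guidance spheres displayed during navigated
#' probe placement.
#'
#' @param current,saved n x 3 matrices of optode positions (mm).
#' @param tol tolerance radius (mm).
#' @return logical vector, one entry per optode.
#' @export
on_position <- function(current, saved, tol = 6) {
  d <- sqrt(rowSums((as_points(current) - as_points(saved))^2))
  d <= tol
}
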