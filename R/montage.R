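# Electrode montages: packaged standard layouts, similarity co-registration
# to a standard head surface, and neighbor lookup.

#' Construct a montage
#'
#' @param labels ordered unique channel labels.
#' @param positions n x 3 matrix of electrode positions in meters
#'   (head frame: x right, y anterior, z superior).
#' @param fiducials optional 3 x 3 matrix with rownames
#'   `nasion`, `lpa`, `rpa`.
#' @return an object of class `eeg_montage`.
#' @export
new_montage <- function(labels, positions, fiducials = NULL) {
  labels <- as.character(labels)
  positions <- as.matrix(positions)
  if (nrow(positions) != length(labels))
    stopf("montage: %d positions for %d labels", nrow(positions), length(labels))
  if (anyDuplicated(labels)) stopf("montage: duplicate labels")
  if (!all(is.finite(positions))) stopf("montage: non-finite positions")
  rownames(positions) <- labels
  if (!is.null(fiducials)) {
    fiducials <- as.matrix(fiducials)
    if (!all(c("nasion", "lpa", "rpa") %in% rownames(fiducials)))
      stopf("montage: fiducials need rows nasion, lpa, rpa")
  }
  structure(list(labels = labels, positions = positions, fiducials = fiducials),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d electrodes%s\n", length(x$labels),
              if (is.null(x$fiducials)) "" else " + fiducials"))
  invisible(x)
}

#' Load a packaged standard montage
#'
#' Standard dense-cap layouts (32, 65 or 129 electrodes, vertex channel
#' `Cz`) shipped as plain electrode-position tables, used as the common head
#' surface that all recordings are co-registered to.
#'
#' @param n_channels one of 32, 65, 129.
#' @return an `eeg_montage`.
#' @export
standard_montage <- function(n_channels) {
  if (!n_channels %in% c(32, 65, 129))
    stopf("standard_montage: no packaged %d-channel layout (32/65/129)", n_channels)
  path <- system.file("extdata", "montages",
                      sprintf("standard_%d.tsv", n_channels),
                      package = "losslessr", mustWork = TRUE)
  read_montage_tsv(path)
}

#' Read an electrode-position table
#'
#' Tab-separated columns `label`, `x`, `y`, `z` (meters); rows whose label is
#' `nasion`, `lpa` or `rpa` are taken as fiducials.
#'
#' @param path file path.
#' @return an `eeg_montage`.
#' @export
read_montage_tsv <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  fid_rows <- tb$label %in% c("nasion", "lpa", "rpa")
  fid <- NULL
  if (any(fid_rows)) {
    fid <- as.matrix(tb[fid_rows, c("x", "y", "z")])
    rownames(fid) <- tb$label[fid_rows]
  }
  el <- tb[!fid_rows, , drop = FALSE]
  new_montage(el$label, as.matrix(el[, c("x", "y", "z")]), fid)
}

write_montage_tsv <- function(m, path) {
  tb <- data.frame(label = m$labels, x = m$positions[, 1],
                   y = m$positions[, 2], z = m$positions[, 3])
  if (!is.null(m$fiducials))
    tb <- rbind(tb, data.frame(label = rownames(m$fiducials),
                               x = m$fiducials[, 1], y = m$fiducials[, 2],
                               z = m$fiducials[, 3]))
  utils::write.table(tb, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Deterministic dense-cap layout: vertex channel Cz plus a Fibonacci spiral
# over the upper spherical cap (radius 0.09 m, cap opening ~115 degrees).
make_cap_montage <- function(n_channels, radius = 0.09) {
  n_spiral <- n_channels - 1L
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n_spiral)
  zmax <- cos(0.12); zmin <- cos(2.0)  # just below Cz down past the ears
  z <- zmax - (i - 0.5) / n_spiral * (zmax - zmin)
  th <- i * golden
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(x = r * cos(th), y = r * sin(th), z = z) * radius
  pos <- rbind(c(0, 0, radius), pos)
  labels <- c("Cz", sprintf("E%03d", i + 1L))
  fid <- rbind(nasion = c(0, radius, -0.25 * radius),
               lpa = c(-radius, 0, -0.25 * radius),
               rpa = c(radius, 0, -0.25 * radius))
  new_montage(labels, pos, fid)
}

#' Co-register a montage to a standard head surface
#'
#' Estimates the least-squares similarity transform (rotation + isotropic
#' scale + translation) mapping this montage onto the standard one, using
#' fiducials when both montages carry all three, otherwise >= 3 shared
#' electrode labels, and applies it to every electrode position.
#'
#' @param m montage to transform.
#' @param standard target montage (e.g. [standard_montage()]).
#' @return the transformed montage; the fitted transform is attached as
#'   attribute `"transform"` (list with `rotation`, `scale`, `translation`).
#' @export
coregister_montage <- function(m, standard) {
  use_fid <- !is.null(m$fiducials) && !is.null(standard$fiducials)
  if (use_fid) {
    from <- m$fiducials[c("nasion", "lpa", "rpa"), , drop = FALSE]
    to <- standard$fiducials[c("nasion", "lpa", "rpa"), , drop = FALSE]
  } else {
    shared <- intersect(m$labels, standard$labels)
    if (length(shared) < 3)
      stopf("coregister_montage: need 3 fiducials or >= 3 shared labels (have %d)",
            length(shared))
    from <- m$positions[shared, , drop = FALSE]
    to <- standard$positions[shared, , drop = FALSE]
  }
  fit <- fit_similarity(from, to)
  newpos <- sweep(m$positions %*% t(fit$rotation) * fit$scale, 2,
                  fit$translation, `+`)
  out <- new_montage(m$labels, newpos, fiducials = {
    if (is.null(m$fiducials)) NULL else {
      f <- sweep(m$fiducials %*% t(fit$rotation) * fit$scale, 2,
                 fit$translation, `+`)
      rownames(f) <- rownames(m$fiducials); f
    }
  })
  radius <- median(sqrt(rowSums(sweep(out$positions, 2,
                                      colMeans(out$positions), `-`)^2)))
  if (radius < 0.05 || radius > 0.15)
    warnf("coregister_montage: fitted head radius %.3f m outside [0.05, 0.15]", radius)
  attr(out, "transform") <- fit
  out
}

# Umeyama/Kabsch similarity fit: minimizes ||to_i - (s R from_i + t)||^2
fit_similarity <- function(from, to) {
  mc <- colMeans(from); sc <- colMeans(to)
  M0 <- sweep(from, 2, mc); S0 <- sweep(to, 2, sc)
  H <- t(M0) %*% S0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  s <- sum(diag(D) * sv$d) / sum(M0^2)
  t_vec <- sc - s * as.vector(R %*% mc)
  list(rotation = R, scale = s, translation = t_vec)
}

# indices of the k nearest electrodes (3D Euclidean) for each given label
nearest_neighbors <- function(m, labels, k) {
  missing <- setdiff(labels, m$labels)
  if (length(missing))
    stopf("montage is missing channel(s): %s", paste(missing, collapse = ", "))
  pos <- m$positions[labels, , drop = FALSE]
  dmat <- as.matrix(stats::dist(pos))
  lapply(seq_along(labels), function(i) {
    ord <- order(dmat[i, ])
    ord <- ord[ord != i]
    labels[ord[seq_len(min(k, length(ord)))]]
  })
}
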