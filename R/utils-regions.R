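# Connected-component labeling and ellipse-equivalent region moments.
# EBImage::bwlabel is 4-connected; segmentation here follows the MATLAB
# regionprops convention (8-connectivity), so diagonal-touching components
# are merged with a small union-find pass over the 4-connected labels.

label8 <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(m)))
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]      # (i,j) vs (i+1,j+1)
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]     # (i+1,j) vs (i,j+1)
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

# Ellipse-equivalent moments of a pixel region, regionprops-style.
# coords: n x 2 matrix of (row, col) indices. The 1/12 term is the variance
# of a unit pixel, so a single pixel has a finite (1-px) equivalent ellipse.
region_moments <- function(coords) {
  n <- nrow(coords)
  ctr <- colMeans(coords)
  dr <- coords[, 1] - ctr[1]; dc <- coords[, 2] - ctr[2]
  urr <- sum(dr * dr) / n + 1 / 12
  ucc <- sum(dc * dc) / n + 1 / 12
  urc <- sum(dr * dc) / n
  common <- sqrt((urr - ucc)^2 + 4 * urc^2)
  l1 <- (urr + ucc + common) / 2
  l2 <- (urr + ucc - common) / 2
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(max(l2, 0))
  ecc <- sqrt(max(1 - l2 / l1, 0))
  # principal eigenvector (direction of the major axis), in (row, col) comps
  if (common < 1e-300) {
    vec <- c(1, 0)
  } else if (abs(urc) > 1e-300) {
    vec <- c(l1 - ucc, urc)
    vec <- vec / sqrt(sum(vec^2))
  } else {
    vec <- if (urr >= ucc) c(1, 0) else c(0, 1)
  }
  if (vec[1] < 0) vec <- -vec                 # canonical: row component >= 0
  list(area = n, centroid = ctr, major = major, minor = minor,
       eccentricity = ecc, axis = vec)
}

# split label matrix into a list of coordinate matrices, ordered by label
label_coords <- function(lab) {
  px <- which(lab > 0, arr.ind = TRUE)
  if (nrow(px) == 0) return(list())
  split.data.frame(px, lab[lab > 0])
}
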