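# 3-D connected-component labeling with 26-connectivity.
#
# EBImage::bwlabel labels each z-frame independently, so full 3-D components
# are assembled here: label every axial slice in 2-D, offset the labels to
# be globally unique, collect the label pairs that touch between adjacent
# slices (all 9 in-plane shifts, i.e. 26-connectivity) as encoded numbers,
# and merge them with a union-find.

label_components_3d <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  lab <- array(0L, d)
  offset <- 0L
  for (k in seq_len(d[3])) {
    m <- mask[, , k]
    if (!any(m)) next
    sl <- EBImage::imageData(EBImage::bwlabel(m * 1))
    storage.mode(sl) <- "integer"
    pos <- sl > 0L
    mx <- max(sl)
    sl[pos] <- sl[pos] + offset
    lab[, , k] <- sl
    offset <- offset + mx
  }
  if (offset == 0L) return(lab)
  K <- as.numeric(offset)

  nx <- d[1]; ny <- d[2]
  encodings <- vector("list", 9L * (d[3] - 1L))
  np <- 0L
  any_slice <- logical(d[3])
  for (k in seq_len(d[3])) any_slice[k] <- any(lab[, , k] > 0L)
  for (k in seq_len(d[3] - 1L)) {
    if (!any_slice[k] || !any_slice[k + 1L]) next
    a <- lab[, , k]
    b <- lab[, , k + 1L]
    for (dx in -1:1) {
      for (dy in -1:1) {
        ax <- max(1L, 1L + dx):min(nx, nx + dx)
        ay <- max(1L, 1L + dy):min(ny, ny + dy)
        av <- a[ax, ay]
        bv <- b[ax - dx, ay - dy]
        keep <- av > 0L & bv > 0L & av != bv
        if (!any(keep)) next
        np <- np + 1L
        encodings[[np]] <- unique(av[keep] * (K + 1) + bv[keep])
      }
    }
  }

  parent <- seq_len(offset)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (np > 0L) {
    enc <- unique(unlist(encodings[seq_len(np)]))
    pa <- as.integer(enc %/% (K + 1))
    pb <- as.integer(enc %% (K + 1))
    for (r in seq_along(pa)) {
      ra <- find_root(pa[r])
      rb <- find_root(pb[r])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }

  roots <- vapply(seq_len(offset), find_root, integer(1))
  relab <- match(roots, sort(unique(roots)))
  nonzero <- lab > 0L
  lab[nonzero] <- relab[lab[nonzero]]
  lab
}

# Component sizes (voxel counts) as a named integer vector, labels as names.
component_sizes <- function(lab) {
  tab <- tabulate(lab[lab > 0L])
  setNames(tab, seq_along(tab))
}

# Most superior slice index (largest k) reached by each label, as an
# integer vector indexed by label.
component_top_slice <- function(lab) {
  n_lab <- max(lab)
  top <- integer(n_lab)
  for (k in seq_len(dim(lab)[3])) {
    u <- unique(as.vector(lab[, , k]))
    u <- u[u > 0L]
    if (length(u)) top[u] <- k
  }
  top
}
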