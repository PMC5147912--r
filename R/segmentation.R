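# union-find used to merge diagonally adjacent components (8-connectivity)
.uf_find <- function(parent, i) {
  while (parent[i] != i) { parent[i] <- parent[parent[i]]; i <- parent[i] }
  i
}

# 8 neighbor offsets (row, col)
.neigh8 <- cbind(rep(-1:1, times = 3), rep(-1:1, each = 3))[-5, , drop = FALSE]

#' Segment nuclei from a DAPI image by local-mean thresholding
#'
#' Pixels brighter than the local mean over an odd square block plus an
#' offset are foreground; the binary map is hole-filled, connected
#' components are labeled with 8-connectivity, and components outside
#' `[min_area, max_area]` or touching the image border are removed.
#' Surviving labels are renumbered 1..K.
#'
#' @param dapi 2-D non-negative numeric matrix (nuclear stain channel).
#' @param block_size odd block side length in pixels (>= 3).
#' @param offset threshold offset in intensity units; `NULL` (default) uses
#'   2\% of the image dynamic range.
#' @param min_area,max_area component area bounds in pixels.
#' @return integer label matrix (0 = background), class `label_mask`, with
#'   attribute `n_labels`.
#' @export
segment_nuclei <- function(dapi, block_size = 51, offset = NULL,
                           min_area = 40, max_area = 1200) {
  stopifnot(is.matrix(dapi), all(dapi >= 0))
  if (block_size < 3 || block_size %% 2 == 0) {
    stop("block_size must be an odd integer >= 3, got ", block_size)
  }
  H <- nrow(dapi); W <- ncol(dapi)
  if (is.null(offset)) offset <- 0.02 * diff(range(dapi))
  w <- (block_size - 1) / 2
  bw <- EBImage::thresh(dapi, w = w, h = w, offset = offset)
  bw <- EBImage::fillHull(bw)
  lbl <- EBImage::imageData(EBImage::bwlabel(bw))
  storage.mode(lbl) <- "integer"
  K <- max(lbl)
  if (K > 0) {
    # bwlabel is 4-connected; merge components that touch diagonally
    a1 <- lbl[-H, -W]; b1 <- lbl[-1, -1]   # down-right diagonal
    a2 <- lbl[-H, -1]; b2 <- lbl[-1, -W]   # down-left diagonal
    sel1 <- a1 > 0 & b1 > 0 & a1 != b1
    sel2 <- a2 > 0 & b2 > 0 & a2 != b2
    pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
    if (nrow(pairs) > 0) {
      parent <- seq_len(K)
      for (r in seq_len(nrow(pairs))) {
        ra <- .uf_find(parent, pairs[r, 1]); rb <- .uf_find(parent, pairs[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(K), function(i) .uf_find(parent, i), integer(1))
      lbl[lbl > 0] <- root[lbl[lbl > 0]]
    }
    areas <- tabulate(lbl, nbins = max(lbl))
    border <- unique(c(lbl[1, ], lbl[H, ], lbl[, 1], lbl[, W]))
    keep <- which(areas >= min_area & areas <= max_area)
    keep <- setdiff(keep, border)
    remap <- integer(max(lbl))
    remap[keep] <- seq_along(keep)
    lbl[lbl > 0] <- remap[lbl[lbl > 0]]
    K <- length(keep)
  }
  structure(lbl, class = c("label_mask", class(lbl)), n_labels = K)
}

#' Cytoplasmic ring masks around segmented nuclei
#'
#' For each nucleus the ring is the set of pixels whose exact Euclidean
#' distance `d` to the nucleus pixel set satisfies
#' `ring_gap < d <= ring_gap + ring_width`, minus all nucleus pixels of
#' any cell.  Pixels claimed by several rings are assigned to the nucleus
#' they are nearest to (ties broken by nearest nucleus centroid, then by
#' lower label id), so rings of different cells are mutually disjoint.
#' Cells whose ring is empty after exclusion are dropped and reported.
#'
#' @param nuclei a `label_mask` from [segment_nuclei()].
#' @param ring_gap gap between nucleus and ring, pixels (>= 0).
#' @param ring_width ring width, pixels (>= 1).
#' @return an object of class `ring_mask_set`: list with `rings` (integer
#'   label matrix sharing the nucleus labels), `labels` (retained labels),
#'   `dropped` (labels with empty rings), `ring_gap`, `ring_width`.
#' @export
make_cytoplasm_rings <- function(nuclei, ring_gap = 1, ring_width = 4) {
  stopifnot(ring_gap >= 0, ring_width >= 1)
  H <- nrow(nuclei); W <- ncol(nuclei)
  K <- max(nuclei)
  rings <- matrix(0L, H, W)
  if (K == 0) {
    return(structure(list(rings = rings, labels = integer(0),
                          dropped = integer(0), ring_gap = ring_gap,
                          ring_width = ring_width),
                     class = "ring_mask_set"))
  }
  fg <- which(nuclei > 0)
  coords <- arrayInd(fg, c(H, W))
  labs <- nuclei[fg]
  pad <- ceiling(ring_gap + ring_width) + 1L
  cents <- cbind(tapply(coords[, 1], labs, mean), tapply(coords[, 2], labs, mean))

  claim_pix <- integer(0); claim_lab <- integer(0); claim_d <- numeric(0)
  for (l in seq_len(K)) {
    sel <- labs == l
    r0 <- max(1L, min(coords[sel, 1]) - pad); r1 <- min(H, max(coords[sel, 1]) + pad)
    c0 <- max(1L, min(coords[sel, 2]) - pad); c1 <- min(W, max(coords[sel, 2]) + pad)
    sub <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(coords[sel, 1] - r0 + 1L, coords[sel, 2] - c0 + 1L)] <- 1
    d <- EBImage::distmap(1 - sub, metric = "euclidean")
    cand <- which(d > ring_gap & d <= ring_gap + ring_width)
    if (length(cand) == 0) next
    ci <- arrayInd(cand, dim(sub))
    gr <- ci[, 1] + r0 - 1L; gc <- ci[, 2] + c0 - 1L
    pix <- (gc - 1L) * H + gr
    keep <- nuclei[pix] == 0L          # exclude every nucleus
    claim_pix <- c(claim_pix, pix[keep])
    claim_lab <- c(claim_lab, rep.int(l, sum(keep)))
    claim_d <- c(claim_d, d[cand][keep])
  }
  if (length(claim_pix) > 0) {
    rr <- (claim_pix - 1L) %% H + 1L
    cc <- (claim_pix - 1L) %/% H + 1L
    cent_d <- sqrt((rr - cents[claim_lab, 1])^2 + (cc - cents[claim_lab, 2])^2)
    # nearest nucleus wins; ties: nearest centroid, then lower label
    o <- order(claim_pix, claim_d, cent_d, claim_lab)
    first <- !duplicated(claim_pix[o])
    rings[claim_pix[o][first]] <- claim_lab[o][first]
  }
  got <- sort(unique(rings[rings > 0]))
  structure(list(rings = rings, labels = got,
                 dropped = setdiff(seq_len(K), got),
                 ring_gap = ring_gap, ring_width = ring_width),
            class = "ring_mask_set")
}

#' Count nuclear boundary pixels ("nuclear vertices") per nucleus
#'
#' A boundary pixel is a labeled pixel with at least one 8-neighbor
#' outside its label (pixels beyond the image edge count as outside).
#' The count shrinks with the nucleus and serves as a proxy for the
#' nuclear shrinkage associated with apoptosis.
#'
#' @param nuclei an integer label matrix.
#' @return named integer vector, one count per label 1..K.
#' @export
count_nuclear_vertices <- function(nuclei) {
  H <- nrow(nuclei); W <- ncol(nuclei)
  K <- max(nuclei)
  if (K == 0) return(setNames(integer(0), character(0)))
  padded <- matrix(0L, H + 2L, W + 2L)
  padded[2:(H + 1), 2:(W + 1)] <- nuclei
  boundary <- matrix(FALSE, H, W)
  for (k in seq_len(nrow(.neigh8))) {
    nb <- padded[(2:(H + 1)) + .neigh8[k, 1], (2:(W + 1)) + .neigh8[k, 2]]
    boundary <- boundary | (nb != nuclei)
  }
  boundary <- boundary & nuclei > 0
  counts <- tabulate(nuclei[boundary], nbins = K)
  setNames(as.integer(counts), as.character(seq_len(K)))
}
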