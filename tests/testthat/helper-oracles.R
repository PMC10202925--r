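# Independent oracles used to cross-check the implementation. These are kept
# deliberately naive (loops, brute force) so they share no code path with the
# package internals they verify.

# direct O(n^2 k^2) correlation with mirrored borders
oracle_conv2 <- function(x, kernel) {
  nr <- nrow(x); nc <- ncol(x)
  kr <- (nrow(kernel) - 1) %/% 2; kc <- (ncol(kernel) - 1) %/% 2
  reflect <- function(i, n) {          # mirror without repeating the edge
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (a in -kr:kr) for (b in -kc:kc) {
      acc <- acc + kernel[a + kr + 1, b + kc + 1] *
        x[reflect(i + a, nr), reflect(j + b, nc)]
    }
    out[i, j] <- acc
  }
  out
}

# queue-based flood fill, 4- or 8-connectivity
oracle_flood_fill <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbrs <- if (connectivity == 8)
    expand.grid(dr = -1:1, dc = -1:1)[-5, ] else
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      pi <- (p - 1L) %% nr + 1L; pj <- (p - 1L) %/% nr + 1L
      for (q in seq_len(nrow(nbrs))) {
        i <- pi + nbrs$dr[q]; j <- pj + nbrs$dc[q]
        if (i >= 1 && i <= nr && j >= 1 && j <= nc &&
            mask[i, j] && lab[i, j] == 0L) {
          lab[i, j] <- cur
          queue <- c(queue, (j - 1L) * nr + i)
        }
      }
    }
  }
  lab
}

# random labeled scene for matching tests: non-overlapping rectangles
random_object_scene <- function(n_objects, n_markers, h = 48L, w = 48L) {
  lab <- matrix(0L, h, w)
  placed <- 0L
  for (try in seq_len(200L)) {
    if (placed >= n_objects) break
    hh <- sample(2:6, 1); ww <- sample(2:6, 1)
    r0 <- sample(seq_len(h - hh), 1); c0 <- sample(seq_len(w - ww), 1)
    patch <- lab[r0:(r0 + hh - 1L), c0:(c0 + ww - 1L)]
    if (all(patch == 0L)) {
      placed <- placed + 1L
      lab[r0:(r0 + hh - 1L), c0:(c0 + ww - 1L)] <- placed
    }
  }
  mx <- sample(0:(w - 1L), n_markers, replace = TRUE)
  my <- sample(0:(h - 1L), n_markers, replace = TRUE)
  list(labels = lab, n_objects = placed,
       markers = marker_set(mx, my, image_shape = c(h, w)))
}

# brute-force point-in-pixel-set matching
oracle_match <- function(labels, markers) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  mk <- as.data.frame(markers)
  pixel_sets <- lapply(ids, function(id) which(labels == id))
  in_object <- integer(nrow(mk))
  nr <- nrow(labels)
  for (m in seq_len(nrow(mk))) {
    lin <- mk$x[m] * nr + mk$y[m] + 1L   # 0-based (x=col, y=row)
    hit <- 0L
    for (k in seq_along(ids)) if (lin %in% pixel_sets[[k]]) { hit <- ids[k]; break }
    in_object[m] <- hit
  }
  tp <- sum(vapply(ids, function(id) any(in_object == id), logical(1)))
  fp <- length(ids) - tp
  fn <- sum(in_object == 0L) +
    sum(vapply(ids, function(id) max(0L, sum(in_object == id) - 1L), integer(1)))
  list(TP = tp, FP = fp, FN = fn)
}

# labels->cell_objects without going through label_objects' labeling
objects_from_labels <- function(labels) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  tab <- do.call(rbind, lapply(ids, function(id) {
    sel <- labels == id
    data.frame(object_id = id, area = sum(sel),
               centroid_x = mean(col(labels)[sel]) - 1,
               centroid_y = mean(row(labels)[sel]) - 1,
               min_row = min(row(labels)[sel]) - 1L,
               min_col = min(col(labels)[sel]) - 1L,
               max_row = max(row(labels)[sel]) - 1L,
               max_col = max(col(labels)[sel]) - 1L)
  }))
  if (is.null(tab))
    tab <- data.frame(object_id = integer(), area = integer(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      min_row = integer(), min_col = integer(),
                      max_row = integer(), max_col = integer())
  structure(list(labels = labels, table = tab, connectivity = 8L),
            class = "cell_objects")
}

# filled disc mask
disc_mask <- function(h, w, cy, cx, r) {
  outer(seq_len(h), seq_len(w), function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2)
}
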