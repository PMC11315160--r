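# e-SLIC baseline: the benchmark adaptation of SLIC to time series. The
# per-pixel series is reduced to its first three principal components (the
# three "color channels" SLIC expects), each component is min-max scaled to
# [0, 1], and SLIC clusters pixels with the combined feature/space distance
#   D = sqrt(d_feat^2 + (d_xy / S)^2 * m^2),   S = sqrt(I / k),
# followed by connectivity enforcement (orphan regions merged into the most
# similar 4-adjacent segment).

slic_init_centers <- function(H, W, k) {
  nc <- max(1L, ceiling(sqrt(k * W / H)))
  nr <- max(1L, ceiling(k / nc))
  rows <- (seq_len(nr) - 0.5) * H / nr
  cols <- (seq_len(nc) - 0.5) * W / nc
  cbind(row = rep(rows, times = nc), col = rep(cols, each = nr))
}

#' SLIC-on-components superpixels (e-SLIC baseline)
#'
#' @param stack a [ts_grid()].
#' @param k requested superpixel count (`1 <= k <=` valid pixel count); the
#'   grid seeding may produce slightly more initial centers.
#' @param compactness spatial weight m of the combined distance; larger
#'   values give more regular, grid-like segments.
#' @param seed unused by the deterministic grid seeding; kept for interface
#'   symmetry with [run_stisebs()].
#' @param iterations SLIC assignment/update rounds.
#' @return a list: `labels` (superpixel [label_grid()]), `superpixels`
#'   ([assemble_superpixels()] result), `pca` (the top-3 component model).
#' @export
eslic_baseline <- function(stack, k, compactness = 0.3, seed = 1L,
                           iterations = 10L) {
  stopifnot(inherits(stack, "ts_grid"))
  pm <- flatten(stack)
  I <- nrow(pm$data)
  if (k < 1L || k > I) stop("k must be between 1 and the valid pixel count")
  model <- fit_pca(pm, variance_target = 1, max_components = 3L)
  F3 <- pca_transform(model, pm$data)
  for (j in seq_len(ncol(F3))) {
    rng <- range(F3[, j])
    F3[, j] <- if (diff(rng) > 0) (F3[, j] - rng[1]) / diff(rng) else 0
  }
  pos <- cbind(pm$index[, 1], pm$index[, 2])
  S <- sqrt(I / k)
  m2 <- compactness^2
  ctr_pos <- slic_init_centers(stack$geometry$height,
                               stack$geometry$width, k)
  # snap centers to the nearest valid pixel feature
  nearest_valid <- function(p) {
    d2 <- (pos[, 1] - p[1])^2 + (pos[, 2] - p[2])^2
    which.min(d2)
  }
  ctr_feat <- F3[apply(ctr_pos, 1L, nearest_valid), , drop = FALSE]
  nk <- nrow(ctr_pos)
  assign_idx <- rep(NA_integer_, I)
  for (it in seq_len(iterations)) {
    best <- rep(Inf, I)
    assign_idx <- rep(NA_integer_, I)
    for (cidx in seq_len(nk)) {
      inwin <- which(abs(pos[, 1] - ctr_pos[cidx, 1]) <= 2 * S &
                     abs(pos[, 2] - ctr_pos[cidx, 2]) <= 2 * S)
      if (!length(inwin)) next
      dxy2 <- (pos[inwin, 1] - ctr_pos[cidx, 1])^2 +
              (pos[inwin, 2] - ctr_pos[cidx, 2])^2
      df2 <- rowSums(sweep(F3[inwin, , drop = FALSE], 2L,
                           ctr_feat[cidx, ])^2)
      D <- df2 + dxy2 / S^2 * m2
      upd <- D < best[inwin]
      best[inwin][upd] <- D[upd]
      assign_idx[inwin][upd] <- cidx
    }
    # pixels outside every search window fall back to the nearest center
    orphan <- which(is.na(assign_idx))
    for (i in orphan) {
      d2 <- (ctr_pos[, 1] - pos[i, 1])^2 + (ctr_pos[, 2] - pos[i, 2])^2
      assign_idx[i] <- which.min(d2)
    }
    for (cidx in seq_len(nk)) {
      mem <- assign_idx == cidx
      if (!any(mem)) next
      ctr_pos[cidx, ] <- colMeans(pos[mem, , drop = FALSE])
      ctr_feat[cidx, ] <- colMeans(F3[mem, , drop = FALSE])
    }
  }
  lab <- matrix(-1L, stack$geometry$height, stack$geometry$width)
  lab[pm$index] <- assign_idx - 1L
  lab <- enforce_connectivity(lab, F3, pm)
  lg <- compact_labels(label_grid(lab, "superpixel", stack$geometry))
  list(labels = lg, superpixels = assemble_superpixels(lg, stack),
       pca = model)
}

# Split each SLIC label into connected components, keep the largest
# component per label, and merge every remaining orphan component into the
# 4-adjacent kept segment with the closest mean feature vector.
enforce_connectivity <- function(lab, feats, pm) {
  valid <- lab >= 0L
  comp_res <- label_patches(label_grid(lab, "superpixel"), 4L)
  cl <- comp_res$labels$labels
  nrc <- nrow(comp_res$table)
  # mean feature and size per component
  cid <- cl[pm$index]
  sums <- rowsum(feats, cid, reorder = TRUE)
  cnt <- as.vector(table(factor(cid, levels = 0:(nrc - 1L))))
  cmean <- sums / cnt
  parent_lab <- comp_res$table$cluster      # original SLIC label per comp
  keep <- logical(nrc)
  for (l in unique(parent_lab)) {
    members <- which(parent_lab == l)
    keep[members[which.max(cnt[members])]] <- TRUE
  }
  final <- ifelse(keep, seq_len(nrc) - 1L, NA_integer_)  # comp -> kept comp
  pr <- neighbor_pairs(nrow(cl), ncol(cl), valid, 4L)
  ca <- cl[pr[, 1]]; cb <- cl[pr[, 2]]
  adj <- unique(rbind(cbind(ca, cb), cbind(cb, ca)))
  adj <- adj[adj[, 1] != adj[, 2], , drop = FALSE]
  todo <- which(is.na(final))
  while (length(todo)) {
    progress <- FALSE
    for (cc in todo) {
      nb <- adj[adj[, 1] == cc - 1L, 2]
      nb_final <- final[nb + 1L]
      nb_final <- nb_final[!is.na(nb_final)]
      if (!length(nb_final)) next
      cand <- unique(nb_final)
      d <- colSums((t(cmean[cand + 1L, , drop = FALSE]) - cmean[cc, ])^2)
      final[cc] <- cand[which.min(d)]
      progress <- TRUE
    }
    todo <- which(is.na(final))
    if (length(todo) && !progress) {
      # isolated island with no kept neighbour: promote its largest comp
      big <- todo[which.max(cnt[todo])]
      final[big] <- big - 1L
    }
  }
  out <- cl
  out[valid] <- final[cl[valid] + 1L]
  out
}
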