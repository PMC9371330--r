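#' Assemble per-subject community trajectories from an ordination
#'
#' Orders each subject's sample coordinates by timepoint, giving one path per
#' subject in the shared ordination space.
#'
#' @param ordination an `ordination` (or a coordinate matrix with sample row
#'   names).
#' @param meta data.frame with columns `sample_id` plus the subject, time and
#'   (optional) group columns.
#' @param subject,time,group column names in `meta`; `group` may be `NULL`.
#' @return object of class `trajectory_set`: list of per-subject coordinate
#'   matrices (rows in time order, rownames = timepoint labels), with
#'   `subjects`, `groups`, `k`.
#' @export
build_trajectories <- function(ordination, meta, subject = "genotype",
                               time = "timepoint", group = NULL) {
  pts <- if (inherits(ordination, "ordination")) ordination$points
         else as.matrix(ordination)
  meta <- as.data.frame(meta)
  meta <- meta[match(rownames(pts), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop_input("metadata does not cover all ordinated samples")
  key <- paste(meta[[subject]], meta[[time]])
  if (anyDuplicated(key))
    stop_input("duplicate subject x timepoint: %s",
               paste(unique(key[duplicated(key)]), collapse = ", "))
  subj <- as.character(meta[[subject]])
  paths <- list(); groups <- character(); gaps <- character()
  all_times <- sort(unique(meta[[time]]))
  for (s in unique(subj)) {
    idx <- which(subj == s)
    if (length(idx) < 2) next
    ord <- idx[order(meta[[time]][idx])]
    m <- pts[ord, , drop = FALSE]
    rownames(m) <- as.character(meta[[time]][ord])
    times_here <- meta[[time]][ord]
    if (!all(all_times[all_times >= min(times_here) &
                       all_times <= max(times_here)] %in% times_here))
      gaps <- c(gaps, s)
    paths[[s]] <- m
    groups[s] <- if (is.null(group)) "all" else as.character(meta[[group]][idx[1]])
  }
  dropped <- setdiff(unique(subj), names(paths))
  if (length(dropped))
    warning(sprintf("dropping %d subject(s) with < 2 timepoints: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  structure(list(paths = paths, subjects = names(paths), groups = groups,
                 k = ncol(pts), gap_subjects = gaps),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("trajectory_set: %d subjects in %d-D space, %d group(s)\n",
              length(x$paths), x$k, length(unique(x$groups))))
  invisible(x)
}

#' Per-subject trajectory geometry
#'
#' Path length (sum of segment lengths), net displacement (first to last
#' point), directionality (net displacement / path length), per-step turning
#' angles, the direction angle of the net displacement in the first two axes,
#' and the reversal count. A reversal is a segment whose projection on the
#' subject's net-displacement vector is negative.
#'
#' @param ts a [build_trajectories()] result.
#' @return object of class `trajectory_metrics`: data.frame with one row per
#'   subject (`path_length`, `net_displacement`, `directionality`,
#'   `direction_angle` in degrees, `n_reversals`, `group`), turning angles in
#'   attribute `"turning_angles"`.
#' @export
trajectory_metrics <- function(ts) {
  stopifnot(inherits(ts, "trajectory_set"))
  ang <- list()
  rows <- lapply(ts$subjects, function(s) {
    m <- ts$paths[[s]]
    seg <- diff(m)
    seg_len <- sqrt(rowSums(seg^2))
    path_len <- sum(seg_len)
    net <- m[nrow(m), ] - m[1, ]
    net_len <- sqrt(sum(net^2))
    turning <- if (nrow(seg) >= 2) {
      vapply(seq_len(nrow(seg) - 1), function(i) {
        a <- seg[i, ]; b <- seg[i + 1, ]
        la <- sqrt(sum(a^2)); lb <- sqrt(sum(b^2))
        if (la == 0 || lb == 0) return(NA_real_)
        acos(pmin(pmax(sum(a * b) / (la * lb), -1), 1)) * 180 / pi
      }, 0)
    } else numeric(0)
    ang[[s]] <<- turning
    reversals <- if (net_len > 0) sum(seg %*% net < 0) else {
      # zero net displacement: count sign flips against the first segment
      sum(seg %*% seg[1, ] < 0)
    }
    dir_angle <- if (net_len > 0)
      atan2(net[2], net[1]) * 180 / pi else NA_real_
    data.frame(subject = s, path_length = path_len,
               net_displacement = net_len,
               directionality = if (path_len > 0 && net_len > 0)
                 net_len / path_len else NA_real_,
               direction_angle = dir_angle, n_reversals = reversals,
               group = unname(ts$groups[s]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("trajectory_metrics", "data.frame"),
            turning_angles = ang)
}

#' Mean group trajectory
#'
#' Per-timepoint centroid of the member subjects' coordinates, connected in
#' time order; one mean path per group.
#'
#' @param ts a [build_trajectories()] result.
#' @param grouping optional named vector subject -> group; defaults to the
#'   groups stored in `ts`.
#' @return a `trajectory_set` whose subjects are the groups.
#' @export
mean_trajectory <- function(ts, grouping = NULL) {
  stopifnot(inherits(ts, "trajectory_set"))
  grouping <- grouping %||% ts$groups
  times <- sort(unique(unlist(lapply(ts$paths, rownames))))
  paths <- list()
  for (gv in unique(grouping)) {
    members <- names(grouping)[grouping == gv]
    cent <- t(vapply(times, function(tp) {
      rows <- do.call(rbind, lapply(members, function(s) {
        m <- ts$paths[[s]]
        if (tp %in% rownames(m)) m[tp, , drop = FALSE] else NULL
      }))
      if (is.null(rows))
        stop_input("empty group x timepoint cell: %s x %s", gv, tp)
      colMeans(rows)
    }, numeric(ts$k)))
    rownames(cent) <- times
    paths[[gv]] <- cent
  }
  structure(list(paths = paths, subjects = names(paths),
                 groups = setNames(names(paths), names(paths)), k = ts$k,
                 gap_subjects = character()),
            class = "trajectory_set")
}

# distance from point p to the closed segment [a, b]
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  den <- sum(ab^2)
  t <- if (den == 0) 0 else pmin(pmax(sum((p - a) * ab) / den, 0), 1)
  sqrt(sum((a + t * ab - p)^2))
}

# mean over vertices of x of the distance to the nearest segment of y
directed_path_distance <- function(x, y) {
  nseg <- max(nrow(y) - 1, 1)
  mean(apply(x, 1, function(p) {
    min(vapply(seq_len(nseg), function(i) {
      a <- y[min(i, nrow(y)), ]
      b <- y[min(i + 1, nrow(y)), ]
      point_segment_distance(p, a, b)
    }, 0))
  }))
}

#' Distance between two community trajectories
#'
#' Symmetrised mean point-to-path distance: the mean over vertices of one
#' path of the distance to the nearest (continuous) segment of the other,
#' averaged over both directions. Single-point paths act as degenerate
#' segments.
#'
#' @param a,b coordinate matrices (rows = ordered timepoints) in the same
#'   space.
#' @return nonnegative scalar; 0 for identical paths.
#' @export
trajectory_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop_input("paths live in different spaces")
  (directed_path_distance(a, b) + directed_path_distance(b, a)) / 2
}

#' Group tests on trajectory geometry
#'
#' One-way ANOVA (with Tukey HSD pairs) on per-subject path length, and on
#' the direction angle of each subject's net displacement measured relative
#' to the grand-mean direction (folded to 0-180 degrees).
#'
#' @param metrics a [trajectory_metrics()] result.
#' @param grouping optional replacement grouping vector aligned with the
#'   metrics rows; defaults to the `group` column.
#' @param use_full_dim if `TRUE`, direction angles use the full-dimensional
#'   cosine against the grand-mean unit displacement; by default the first
#'   two axes are used.
#' @param ts the `trajectory_set` the metrics came from (needed for
#'   full-dimensional directions).
#' @return list with `length_anova`, `direction_anova` (each a list of
#'   `table` (df, F, p) and `tukey`), and the per-subject relative angles.
#' @export
trajectory_group_tests <- function(metrics, grouping = NULL, ts = NULL,
                                   use_full_dim = FALSE) {
  stopifnot(inherits(metrics, "trajectory_metrics"))
  df <- as.data.frame(metrics)
  df$group <- grouping %||% df$group
  sizes <- table(df$group)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning(sprintf("excluding group(s) with < 2 subjects: %s",
                    paste(small, collapse = ", ")))
    df <- df[!df$group %in% small, , drop = FALSE]
  }
  if (length(unique(df$group)) < 2)
    stop_input("need at least two groups with >= 2 subjects")
  df$group <- factor(df$group)

  # net-displacement unit vectors per subject
  dirs <- if (!is.null(ts)) {
    t(vapply(df$subject, function(s) {
      m <- ts$paths[[s]]
      v <- m[nrow(m), ] - m[1, ]
      if (!use_full_dim) v <- v[1:2]
      l <- sqrt(sum(v^2)); if (l > 0) v / l else v * NA_real_
    }, numeric(if (use_full_dim) ts$k else 2)))
  } else {
    th <- df$direction_angle * pi / 180
    cbind(cos(th), sin(th))
  }
  grand <- colMeans(dirs, na.rm = TRUE)
  grand <- grand / sqrt(sum(grand^2))
  rel_angle <- acos(pmin(pmax(dirs %*% grand, -1), 1)) * 180 / pi
  df$rel_angle <- as.vector(rel_angle)

  run_aov <- function(resp) {
    dat <- df[is.finite(df[[resp]]), , drop = FALSE]
    fit <- aov(stats::as.formula(paste(resp, "~ group")), data = dat)
    an <- suppressWarnings(anova(fit))  # perfect fits trip an anova warning
    f <- an$`F value`[1]; p <- an$`Pr(>F)`[1]
    if (sum(an$`Sum Sq`) < 1e-24) { f <- 0; p <- 1 }  # all values identical
    list(table = data.frame(df = an$Df[1], F = f, p = p),
         tukey = as.data.frame(TukeyHSD(fit)$group))
  }
  list(length_anova = run_aov("path_length"),
       direction_anova = run_aov("rel_angle"),
       angles = setNames(df$rel_angle, df$subject))
}

#' Leave-one-OTU-out trajectory influence
#'
#' Removes each OTU in turn, re-runs the fixed ordination protocol
#' (CSS normalisation, Hellinger transform, Bray-Curtis, PCoA), aligns the
#' recomputed sample coordinates to the originals by orthogonal Procrustes
#' (rotation/reflection + translation, no scaling), recomputes mean group
#' trajectories, and scores the OTU by the mean over groups of
#' [trajectory_distance()] between original and recomputed mean paths.
#' Significance is a z-score of the influence against the all-OTU influence
#' distribution.
#'
#' @param table an [otu_table()] of true (non-control) samples.
#' @param grouping column name in the sample metadata giving the groups.
#' @param subject,time metadata column names for trajectory assembly.
#' @param n_axes number of PCoA axes used for the trajectories; `NULL` (the
#'   default) uses all positive-eigenvalue axes, so trajectory geometry is
#'   measured in the full metric embedding.
#' @param z_cut z-score flag threshold, default 2.
#' @return object of class `influence_result`: data.frame with `otu_id`,
#'   `influence`, `z`, `significant`.
#' @export
otu_removal_influence <- function(table, grouping = "subpopulation",
                                  subject = "genotype", time = "timepoint",
                                  n_axes = NULL, z_cut = 2) {
  stopifnot(inherits(table, "otu_table"))
  meta <- table$sample_meta
  protocol <- function(counts) {
    keep <- rowSums(counts) > 0
    am <- suppressWarnings(css_normalize(counts[keep, , drop = FALSE]))
    d <- bray_curtis(hellinger_transform(am))
    ord <- pcoa(d, k = 2)
    if (is.null(n_axes)) ord$all_points
    else ord$all_points[, seq_len(min(n_axes, ncol(ord$all_points))),
                        drop = FALSE]
  }
  pts0 <- protocol(table$counts)
  ts0 <- build_trajectories(pts0, meta, subject, time, grouping)
  mt0 <- mean_trajectory(ts0)
  otus <- colnames(table$counts)
  infl <- vapply(seq_along(otus), function(j) {
    counts <- table$counts[, -j, drop = FALSE]
    if (all(table$counts[, j] == 0)) return(0)
    pts <- protocol(counts)
    shared <- intersect(rownames(pts0), rownames(pts))
    kk <- min(ncol(pts0), ncol(pts))
    pts <- procrustes_align(pts0[shared, seq_len(kk), drop = FALSE],
                            pts[shared, seq_len(kk), drop = FALSE])
    tsj <- suppressWarnings(
      build_trajectories(pts, meta[meta$sample_id %in% shared, , drop = FALSE],
                         subject, time, grouping))
    mtj <- mean_trajectory(tsj)
    groups <- intersect(mt0$subjects, mtj$subjects)
    mean(vapply(groups, function(gv)
      trajectory_distance(mt0$paths[[gv]][, seq_len(kk), drop = FALSE],
                          mtj$paths[[gv]]), 0))
  }, 0)
  z <- (infl - mean(infl)) / sd(infl)
  out <- data.frame(otu_id = otus, influence = infl, z = z,
                    significant = z > z_cut, row.names = NULL)
  structure(out[order(-out$influence), ],
            class = c("influence_result", "data.frame"),
            n_axes = n_axes, z_cut = z_cut)
}

# orthogonal Procrustes: rotate/reflect + translate y onto x (no scaling)
procrustes_align <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  s <- svd(crossprod(yc, xc))
  rot <- s$u %*% t(s$v)
  out <- yc %*% rot
  out <- sweep(out, 2, cx, "+")
  rownames(out) <- rownames(y)
  out
}

#' Export trajectories in long format
#'
#' @param ts a `trajectory_set`.
#' @param path optional TSV output path.
#' @return data.frame with `subject`, `timepoint` and one column per axis.
#' @export
trajectories_long <- function(ts, path = NULL) {
  out <- do.call(rbind, lapply(ts$subjects, function(s) {
    m <- ts$paths[[s]]
    data.frame(subject = s, timepoint = rownames(m), m, row.names = NULL)
  }))
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
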