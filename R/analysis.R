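#' Titration profile of a run
#'
#' The sequence of (window temperature, window-mean IFP_CS) points for
#' one titration, preceded by the anchor state `(t_start, -1)`: the
#' equilibrated native complex, which by definition scores -1 against
#' itself.
#'
#' @param run a `ttmd_run`.
#' @return object of class `ttmd_profile` with `points` (data frame) and
#'   `anchor`.
#' @export
titration_profile <- function(run) {
  if (length(run$windows) == 0) stop("empty run: no completed windows")
  pts <- data.frame(
    temperature = vapply(run$windows, `[[`, 0, "temperature"),
    mean_ifpcs = vapply(run$windows, `[[`, 0, "mean_ifpcs"))
  structure(list(points = pts,
                 anchor = c(temperature = run$ramp$t_start, mean_ifpcs = -1)),
            class = "ttmd_profile")
}

#' MS coefficient of a titration profile
#'
#' The slope of the straight line joining the titration's initial state
#' (the anchor, mean IFP_CS -1 at the ramp start) and its final state
#' (the last completed window). The temperature axis is measured in
#' ramp-increment units and the value capped at 1, so MS spans 0 (the
#' binding mode fully retained through the whole ramp) to 1 (complete
#' loss within the first window); the raw per-kelvin slope is reported
#' alongside.
#'
#' @param profile a [titration_profile()].
#' @param ramp the `ttmd_ramp` the run used.
#' @return object of class `ttmd_ms` with elements `ms`, `ms_per_kelvin`,
#'   `t_end_used`, `mean_ifpcs_at_end`, `n_increments`.
#' @export
ms_coefficient <- function(profile, ramp) {
  if (nrow(profile$points) == 0) stop("empty profile")
  t_end <- profile$points$temperature[nrow(profile$points)]
  mean_end <- profile$points$mean_ifpcs[nrow(profile$points)]
  t_start <- unname(profile$anchor["temperature"])
  if (t_end < t_start || t_end > ramp$t_end)
    stop("profile temperatures inconsistent with ramp")
  n_inc <- (t_end - t_start) / ramp$increment
  ms <- min(1, (mean_end + 1) / max(1, n_inc))
  structure(list(ms = ms,
                 ms_per_kelvin = if (t_end > t_start) (mean_end + 1) / (t_end - t_start)
                                 else NA_real_,
                 t_end_used = t_end, mean_ifpcs_at_end = mean_end,
                 n_increments = n_inc),
            class = "ttmd_ms")
}

#' Aggregate replicate MS values by trimmed mean
#'
#' Discards exactly one highest and one lowest value (one instance each
#' on ties) and averages the rest: with the default five replicates,
#' three survive.
#'
#' @param ms_values numeric vector of replicate MS coefficients (>= 3).
#' @return object of class `ttmd_replicates` with `values`, `retained`,
#'   `aggregated_ms`.
#' @export
aggregate_replicates <- function(ms_values) {
  if (length(ms_values) < 3) stop("need at least 3 replicate MS values")
  s <- sort(ms_values)
  retained <- s[2:(length(s) - 1)]
  structure(list(values = ms_values, retained = retained,
                 aggregated_ms = mean(retained)),
            class = "ttmd_replicates")
}

#' Rank poses by aggregated MS
#'
#' Lower MS means higher persistence of the native binding mode, so rank
#' 1 is the most stable pose. Ties are broken by pose id and flagged.
#'
#' @param replicate_sets named list: pose id -> `ttmd_replicates` (or a
#'   bare numeric aggregated MS).
#' @return data frame with columns `pose`, `aggregated_ms`, `rank`, `tied`.
#' @export
rank_poses <- function(replicate_sets) {
  if (length(replicate_sets) == 0) stop("no poses to rank")
  ids <- names(replicate_sets)
  if (is.null(ids) || any(ids == "")) stop("replicate_sets must be named by pose id")
  ms <- vapply(replicate_sets, function(x)
    if (inherits(x, "ttmd_replicates")) x$aggregated_ms else as.numeric(x), 0)
  ord <- order(ms, ids)
  out <- data.frame(pose = ids[ord], aggregated_ms = unname(ms[ord]),
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  out$tied <- duplicated(out$aggregated_ms) | duplicated(out$aggregated_ms, fromLast = TRUE)
  out
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares fit of `mobile` onto `target` using the atoms in
#' `subset`, constrained to a proper rotation (det = +1).
#'
#' @param mobile,target n x 3 coordinate matrices.
#' @param subset row indices used for the fit (default all rows; at least
#'   3 non-collinear atoms).
#' @return list with `rotation` (3 x 3), `translation`, `rmsd` (fitted,
#'   over the subset), and `fitted` (all of `mobile` transformed).
#' @export
superpose_kabsch <- function(mobile, target, subset = NULL) {
  stopifnot(ncol(mobile) == 3, ncol(target) == 3, nrow(mobile) == nrow(target))
  if (is.null(subset)) subset <- seq_len(nrow(mobile))
  if (length(subset) < 3) stop("degenerate subset: need at least 3 atoms")
  A <- mobile[subset, , drop = FALSE]; B <- target[subset, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  sv <- svd(H)
  if (sv$d[2] < 1e-10) stop("degenerate subset: atoms are collinear")
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- sweep(tcrossprod(sweep(mobile, 2, ca), R), 2, cb, "+")
  rmsd <- sqrt(mean(rowSums((fitted[subset, , drop = FALSE] - B)^2)))
  list(rotation = R, translation = cb - as.numeric(R %*% ca), rmsd = rmsd,
       fitted = fitted)
}

#' Backbone and ligand RMSD along a titration run
#'
#' Each frame is superposed on the reference protein backbone
#' (N, CA, C, O of standard residues); the ligand RMSD is then computed
#' on heavy atoms in that fitted frame, without refitting, so it reflects
#' motion relative to the binding site. No ligand symmetry correction is
#' applied.
#'
#' @param run a `ttmd_run`.
#' @param reference a `ttmd_frame` (default the run's starting pose).
#' @return data frame with one row per frame: `window`, `frame`, `time`,
#'   `temperature`, `ifp_cs`, `backbone_rmsd`, `ligand_rmsd`.
#' @export
rmsd_series <- function(run, reference = NULL) {
  model <- run$model
  if (is.null(reference)) reference <- run$pose_frame
  check_frame_congruent(model, reference)
  bb <- which(model$protein$name %in% c("N", "CA", "C", "O") &
              !model$protein$is_h & !model$protein$is_metal)
  if (length(bb) < 3) stop("missing backbone atoms (need N, CA, C, O records)")
  lig_heavy <- which(!model$ligand$is_h)
  rows <- list()
  for (w in seq_along(run$windows)) {
    win <- run$windows[[w]]
    for (j in seq_along(win$frames)) {
      fr <- win$frames[[j]]
      # fit the whole complex by the protein backbone, then measure the ligand
      allref <- rbind(reference$protein_xyz, reference$ligand_xyz)
      allmov <- rbind(fr$protein_xyz, fr$ligand_xyz)
      fit <- superpose_kabsch(allmov, allref, bb)
      np <- nrow(fr$protein_xyz)
      lig_fit <- fit$fitted[np + lig_heavy, , drop = FALSE]
      lig_ref <- reference$ligand_xyz[lig_heavy, , drop = FALSE]
      rows[[length(rows) + 1]] <- data.frame(
        window = w, frame = fr$index, time = fr$time,
        temperature = win$temperature,
        ifp_cs = win$frame_scores[[j]]$ifp_cs,
        backbone_rmsd = fit$rmsd,
        ligand_rmsd = sqrt(mean(rowSums((lig_fit - lig_ref)^2))))
    }
  }
  do.call(rbind, rows)
}

#' Most frequently contacted protein residues
#'
#' Ranks protein residues by the fraction of trajectory frames in which
#' any of their heavy atoms lies within `cutoff` of any ligand heavy
#' atom; reports at most `top_n` residues (ties broken by residue order).
#' Replaces a per-residue force-field energy decomposition with a purely
#' geometric contact frequency.
#'
#' @param run a `ttmd_run`.
#' @param cutoff heavy-atom distance cutoff, Angstrom.
#' @param top_n maximum rows reported.
#' @return data frame with `residue`, `n_frames`, `frequency`.
#' @export
contact_frequency_report <- function(run, cutoff = 4.5, top_n = 25) {
  if (cutoff <= 0) stop("cutoff must be positive")
  model <- run$model
  ph <- which(!model$protein$is_h)
  lh <- which(!model$ligand$is_h)
  reskeys <- model$protein$reskey[ph]
  counts <- setNames(integer(model$r), model$residue_order)
  n_frames <- 0L
  for (win in run$windows) for (fr in win$frames) {
    n_frames <- n_frames + 1L
    D <- pair_dist(fr$protein_xyz[ph, , drop = FALSE],
                   fr$ligand_xyz[lh, , drop = FALSE])
    hit <- unique(reskeys[rowSums(D <= cutoff) > 0])
    counts[hit] <- counts[hit] + 1L
  }
  keep <- which(counts > 0)
  ord <- keep[order(-counts[keep], keep)]
  ord <- ord[seq_len(min(top_n, length(ord)))]
  data.frame(residue = model$residue_order[ord],
             n_frames = unname(counts[ord]),
             frequency = unname(counts[ord]) / max(1L, n_frames),
             stringsAsFactors = FALSE)
}

#' Export run analyses as plots and tables
#'
#' Writes the three standard analysis plots (titration profile, contact
#' frequency, RMSD/IFP_CS time series) as PNG plus their underlying CSV
#' tables, and, when a pose ranking is supplied, the ranking table as CSV
#' and JSON. Data files contain no timestamps, so identical inputs give
#' identical files.
#'
#' @param run a `ttmd_run`.
#' @param dir output directory (created if needed).
#' @param ranking optional data frame from [rank_poses()].
#' @param prefix file-name prefix.
#' @return named character vector of the files written.
#' @export
export_report <- function(run, dir, ranking = NULL, prefix = "ttmd") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  pth <- function(name) file.path(dir, paste0(prefix, "_", name))

  prof <- titration_profile(run)
  prof_df <- rbind(data.frame(temperature = prof$anchor["temperature"],
                              mean_ifpcs = prof$anchor["mean_ifpcs"],
                              row.names = NULL),
                   prof$points)
  utils::write.csv(prof_df, pth("titration_profile.csv"), row.names = FALSE)
  paths["profile_csv"] <- pth("titration_profile.csv")
  grDevices::png(pth("titration_profile.png"), width = 800, height = 600)
  plot(prof_df$temperature, prof_df$mean_ifpcs, type = "b", pch = 19,
       xlab = "temperature (K)", ylab = "window mean IFP_CS",
       main = "Titration profile", ylim = c(-1, 0))
  grDevices::dev.off()
  paths["profile_png"] <- pth("titration_profile.png")

  cf <- contact_frequency_report(run)
  utils::write.csv(cf, pth("contact_frequency.csv"), row.names = FALSE)
  paths["contacts_csv"] <- pth("contact_frequency.csv")
  grDevices::png(pth("contact_frequency.png"), width = 800, height = 600)
  graphics::barplot(cf$frequency, names.arg = cf$residue, las = 2,
                    cex.names = 0.6, ylab = "fraction of frames in contact",
                    main = "Most contacted residues (4.5 A)")
  grDevices::dev.off()
  paths["contacts_png"] <- pth("contact_frequency.png")

  ts <- rmsd_series(run)
  utils::write.csv(ts, pth("timeseries.csv"), row.names = FALSE)
  paths["timeseries_csv"] <- pth("timeseries.csv")
  grDevices::png(pth("timeseries.png"), width = 800, height = 600)
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  plot(ts$time / 1000, ts$ligand_rmsd, type = "l", col = "firebrick",
       xlab = "time (ns)", ylab = "RMSD (A)", main = "Ligand / backbone RMSD")
  graphics::lines(ts$time / 1000, ts$backbone_rmsd, col = "steelblue")
  graphics::legend("topleft", c("ligand", "backbone"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  plot(ts$time / 1000, ts$ifp_cs, type = "l", xlab = "time (ns)",
       ylab = "IFP_CS", ylim = c(-1, 0), main = "IFP_CS")
  grDevices::dev.off()
  paths["timeseries_png"] <- pth("timeseries.png")

  if (!is.null(ranking)) {
    utils::write.csv(ranking, pth("pose_ranking.csv"), row.names = FALSE)
    paths["ranking_csv"] <- pth("pose_ranking.csv")
    jsonlite::write_json(ranking, pth("pose_ranking.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    paths["ranking_json"] <- pth("pose_ranking.json")
  }
  paths
}
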