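# Self-supervised training: patch preparation, augmentation stream, Adam.

crop_pad_mat <- function(m, origin, patch) {
  H <- nrow(m); W <- ncol(m)
  ii <- origin[1]:min(origin[1] + patch - 1, H)
  jj <- origin[2]:min(origin[2] + patch - 1, W)
  out <- matrix(0, patch, patch)
  out[seq_along(ii), seq_along(jj)] <- m[ii, jj]
  out
}

# dihedral augmentations: rot in 0:3 (multiples of 90 deg, counter-clockwise)
# then optional horizontal flip (columns reversed)
aug_mat <- function(m, rot, flip) {
  for (r in seq_len(rot %% 4)) m <- t(m)[nrow(t(m)):1, , drop = FALSE]
  if (flip) m <- m[, ncol(m):1, drop = FALSE]
  m
}

aug_arr <- function(a, rot, flip) {
  if (rot %% 4 == 0 && !flip) return(a)
  out <- NULL
  for (g in seq_len(dim(a)[3])) {
    s <- aug_mat(a[, , g], rot, flip)
    if (is.null(out)) out <- array(0, c(nrow(s), ncol(s), dim(a)[3]),
                                   dimnames = dimnames(a))
    out[, , g] <- s
  }
  out
}

#' Prepare a dataset for training and inference
#'
#' Filters transcripts, rasterises the expression map, types every nucleus by
#' Spearman correlation with the reference profile, computes per-cell
#' expansion masks (circular or rotated elliptical by type), derives training
#' marker sets and per-cell marker maps, and crops both patch grids. All of
#' this depends only on the inputs, so it is computed once.
#'
#' @param transcripts Transcript data.frame (filtered with
#'   [filter_transcripts()] using `min_qv` / `exclude_patterns`).
#' @param nuclei_mask Integer nuclei label mask.
#' @param profile An `sst_profile` (carries the elongated-type flags).
#' @param patch_size Patch side length, default 48.
#' @param min_qv,exclude_patterns Passed to [filter_transcripts()].
#' @param round_kernel_d,alpha,l_t,l_vm Expansion-mask parameters.
#' @param marker_percentile,commonality_threshold Passed to
#'   [derive_markers()].
#' @param pixel_size Microns per pixel.
#' @return List of class `sst_prep`.
#' @export
prepare_dataset <- function(transcripts, nuclei_mask, profile,
                            patch_size = 48, min_qv = 20,
                            exclude_patterns = c("NegPrb", "Blank-"),
                            round_kernel_d = 20, alpha = 0.9, l_t = 60,
                            l_vm = 3, marker_percentile = 0.10,
                            commonality_threshold = 1 / 3, pixel_size = 1) {
  H <- nrow(nuclei_mask); W <- ncol(nuclei_mask)
  filtered <- filter_transcripts(transcripts, min_qv, exclude_patterns)
  panel <- colnames(profile)
  map <- build_expression_map(filtered, H, W, panel, pixel_size)
  nuclei_summary <- summarise_nuclei(map, nuclei_mask, profile)
  markers <- derive_markers(profile, marker_percentile, commonality_threshold)

  ids <- as.integer(nuclei_summary$cell_id)
  expansion <- vector("list", length(ids))
  names(expansion) <- nuclei_summary$cell_id
  for (k in seq_along(ids)) {
    row <- nuclei_summary[k, ]
    expansion[[k]] <- expansion_mask(
      nuclei_mask == ids[k], elongated = row$elongated, ecc = row$ecc,
      orientation = row$orientation, round_kernel_d = round_kernel_d,
      alpha = alpha, l_t = l_t, l_vm = l_vm)
  }
  # per-type marker presence maps (any marker transcript at the pixel)
  presence <- function(set) {
    acc <- matrix(0, H, W)
    for (g in intersect(set, panel)) acc <- acc + map[, , g]
    acc > 0
  }
  pos_presence <- lapply(markers$positive, presence)
  neg_presence <- lapply(markers$negative, presence)
  k3 <- matrix(TRUE, 3, 3)
  m_pos <- m_neg <- vector("list", length(ids))
  names(m_pos) <- names(m_neg) <- nuclei_summary$cell_id
  for (k in seq_along(ids)) {
    ty <- nuclei_summary$type[k]
    if (!ty %in% names(pos_presence)) {  # typing fallback: no marker signal
      m_pos[[k]] <- m_neg[[k]] <- matrix(FALSE, H, W)
      next
    }
    m_pos[[k]] <- binary_dilate(pos_presence[[ty]] & expansion[[k]], k3)
    m_neg[[k]] <- binary_dilate(neg_presence[[ty]] & expansion[[k]], k3)
  }

  structure(list(
    map = map, nuclei_mask = nuclei_mask, profile = profile,
    transcripts = filtered, nuclei_summary = nuclei_summary,
    markers = markers, expansion = expansion, m_pos = m_pos, m_neg = m_neg,
    patch_size = patch_size,
    patches_primary = crop_patches(map, nuclei_mask, patch_size, "primary"),
    patches_shifted = crop_patches(map, nuclei_mask, patch_size, "shifted"),
    params_morph = list(round_kernel_d = round_kernel_d, alpha = alpha,
                        l_t = l_t, l_vm = l_vm)),
    class = "sst_prep")
}

# assemble per-cell training targets for one patch (before augmentation)
patch_targets <- function(prep, patch) {
  ids <- sort(unique(patch$nuclei[patch$nuclei > 0]))
  ps <- prep$patch_size
  x_nuc <- lapply(ids, function(i) (patch$nuclei == i) * 1)
  e_c <- lapply(as.character(ids), function(i)
    crop_pad_mat(prep$expansion[[i]] * 1, patch$origin, ps))
  mp <- lapply(as.character(ids), function(i)
    crop_pad_mat(prep$m_pos[[i]] * 1, patch$origin, ps))
  mn <- lapply(as.character(ids), function(i)
    crop_pad_mat(prep$m_neg[[i]] * 1, patch$origin, ps))
  list(cell_ids = ids, x_nuc = x_nuc, e_c = e_c, m_pos = mp, m_neg = mn,
       nuc_union = (patch$nuclei > 0) * 1)
}

#' Deterministic shuffled, augmented training stream
#'
#' Emits indices into the non-empty primary-grid patches together with one of
#' the 8 dihedral augmentations (rotation by 0/90/180/270 degrees, optionally
#' followed by a horizontal flip), drawn uniformly. The order of patches is
#' randomised; when fewer patches exist than iterations the stream cycles,
#' reshuffling each epoch. Only primary-grid patches are ever used for
#' training.
#'
#' @param n_patches Number of (non-empty) training patches.
#' @param n_iterations Stream length.
#' @param seed Integer seed; the stream is deterministic given it.
#' @return data.frame with columns `patch`, `rot` (0-3), `flip` (logical).
#' @export
make_training_stream <- function(n_patches, n_iterations, seed) {
  if (n_patches < 1) stop("no non-empty training patches")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  order <- integer(0)
  while (length(order) < n_iterations) {
    order <- c(order, sample.int(n_patches))
  }
  order <- order[seq_len(n_iterations)]
  aug <- sample.int(8, n_iterations, replace = TRUE) - 1L
  data.frame(patch = order, rot = aug %% 4L, flip = aug >= 4L)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, weight_decay,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Training configuration
#'
#' Defaults follow the reference training schedule: 4000 iterations of Adam
#' at a fixed learning rate of 1e-5, first/second moment estimates 0.9/0.999,
#' weight decay 1e-4, 48 x 48 patches, all loss weights 1.
#'
#' @param n_iterations Training steps.
#' @param learning_rate Fixed Adam learning rate.
#' @param adam_beta1,adam_beta2 Moment estimates.
#' @param weight_decay L2 weight decay added to the gradient.
#' @param patch_size Patch side length.
#' @param channels Reference-backbone channel width.
#' @param backbone Registered backbone name.
#' @param weights A [loss_weights()].
#' @param reductions Pixel reductions of the cross-entropy losses (see
#'   [patch_losses()]). The default is the size-balance convention: the
#'   cell-calling and positive-marker losses act at pixel-sum scale
#'   (commensurate with the over-segmentation and negative-marker sums they
#'   are balanced against), while nuclei encapsulation stays a per-pixel
#'   mean, anchoring nuclei without fighting the cell-calling expansion
#'   pixel for pixel.
#' @param rng_seed Global seed controlling weight init, shuffling and
#'   augmentation.
#' @export
train_config <- function(n_iterations = 4000, learning_rate = 1e-5,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         weight_decay = 1e-4, patch_size = 48, channels = 16,
                         backbone = "ref_unet", weights = loss_weights(),
                         reductions = c(ne = "mean", cc = "sum", pos = "sum"),
                         rng_seed = 42L) {
  stopifnot(all(reductions %in% c("mean", "sum")),
            all(c("ne", "cc", "pos") %in% names(reductions)))
  structure(list(n_iterations = n_iterations, learning_rate = learning_rate,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 weight_decay = weight_decay, patch_size = patch_size,
                 channels = channels, backbone = backbone, weights = weights,
                 reductions = reductions,
                 rng_seed = as.integer(rng_seed)),
            class = "sst_train_config")
}

#' Train the segmentation backbone on a prepared dataset
#'
#' Runs `n_iterations` steps of Adam on the weighted sum of the six losses.
#' One patch is processed per step; the effective batch is the patch's cells.
#' Raw counts are fed unnormalised. Weights are He-initialised. The seeding
#' order is: weight init first, then the stream (shuffle + augmentation).
#'
#' @param prep An `sst_prep` from [prepare_dataset()].
#' @param config A [train_config()].
#' @param init_params Optional starting weights (default: fresh He init).
#' @param checkpoint_path Optional path; final weights are saved there (RDS)
#'   with the config and a config hash embedded.
#' @param log_path Optional CSV path for the per-step loss breakdown.
#' @param verbose Print progress every 50 steps.
#' @return List with `params`, `loss_log` (data.frame: step, the six parts,
#'   total), and `config`.
#' @export
train_model <- function(prep, config = train_config(), init_params = NULL,
                        checkpoint_path = NULL, log_path = NULL,
                        verbose = FALSE) {
  bk <- get_backbone(config$backbone)
  G <- dim(prep$map)[3]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$rng_seed)
  params <- if (is.null(init_params)) bk$init(G + 1, config$channels) else
    init_params

  usable <- which(!vapply(prep$patches_primary, `[[`, logical(1), "empty"))
  if (length(usable) == 0) stop("no non-empty training patches")
  targets <- lapply(prep$patches_primary[usable],
                    function(p) patch_targets(prep, p))

  log <- data.frame(step = integer(), ne = numeric(), cc = numeric(),
                    os = numeric(), ov = numeric(), pos = numeric(),
                    neg = numeric(), total = numeric())
  if (config$n_iterations == 0) {
    return(list(params = params, loss_log = log, config = config))
  }
  stream <- make_training_stream(length(usable), config$n_iterations,
                                 config$rng_seed + 1L)
  state <- adam_init(params)

  for (step in seq_len(config$n_iterations)) {
    s <- stream[step, ]
    patch <- prep$patches_primary[[usable[s$patch]]]
    tg <- targets[[s$patch]]
    expr <- aug_arr(patch$map, s$rot, s$flip)
    nuc <- aug_mat(patch$nuclei, s$rot, s$flip)
    tga <- list(cell_ids = tg$cell_ids,
                x_nuc = lapply(tg$x_nuc, aug_mat, rot = s$rot, flip = s$flip),
                e_c = lapply(tg$e_c, aug_mat, rot = s$rot, flip = s$flip),
                m_pos = lapply(tg$m_pos, aug_mat, rot = s$rot, flip = s$flip),
                m_neg = lapply(tg$m_neg, aug_mat, rot = s$rot, flip = s$flip),
                nuc_union = aug_mat(tg$nuc_union, s$rot, s$flip))
    probs <- forward_patch(list(expression = expr, nuclei = nuc,
                                cell_ids = tg$cell_ids),
                           params, config$backbone, keep_cache = TRUE)
    q_hat <- lapply(seq_along(tg$cell_ids),
                    function(m) probs$foreground[, , m])
    pl <- patch_losses(q_hat, tga, config$weights, gradients = TRUE,
                       reductions = config$reductions)
    if (!is.finite(pl$total)) {
      stop(sprintf("non-finite loss at step %d (%s)", step,
                   paste(sprintf("%s=%.3g", names(pl$parts), pl$parts),
                         collapse = ", ")))
    }
    grads <- NULL
    for (m in seq_along(tg$cell_ids)) {
      q <- q_hat[[m]]
      dz <- pl$grad[[m]] * q * (1 - q)  # chain through 2-way softmax
      dlogits <- array(0, c(dim(q), 2))
      dlogits[, , 1] <- -dz
      dlogits[, , 2] <- dz
      g <- bk$backward(params, probs$caches[[m]], dlogits)
      grads <- if (is.null(grads)) g else
        stats::setNames(lapply(names(g), function(nm) grads[[nm]] + g[[nm]]),
                        names(g))
    }
    upd <- adam_step(params, grads, state, config$learning_rate,
                     config$adam_beta1, config$adam_beta2,
                     config$weight_decay)
    params <- upd$params; state <- upd$state
    log[step, ] <- c(step, pl$parts, pl$total)
    if (verbose && step %% 50 == 0) {
      message(sprintf("step %d: total %.4f", step, pl$total))
    }
  }
  if (!is.null(log_path)) utils::write.csv(log, log_path, row.names = FALSE)
  if (!is.null(checkpoint_path)) {
    save_checkpoint(params, config, checkpoint_path)
  }
  list(params = params, loss_log = log, config = config)
}

#' Save / load a weight checkpoint
#'
#' Single portable RDS file embedding the weights, the training config and a
#' hash of the config for provenance checks.
#'
#' @param params Backbone weights.
#' @param config The [train_config()] used.
#' @param path File path.
#' @export
save_checkpoint <- function(params, config, path) {
  tmp <- tempfile()
  saveRDS(config, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  saveRDS(list(params = params, config = config, config_hash = hash), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
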