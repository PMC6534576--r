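#' Generate a synthetic capillary network inside a mask
#'
#' Emulates the architecture of the myocardial capillary bed: capillary
#' segments ("tracts") of bounded length following a smooth fiber direction
#' field, laid down with even-spacing streamline placement until the
#' vessel-length-density (VLD) budget is filled, whose ends attach to
#' neighbouring tracts as T-junctions. Branch points are the attachment
#' sites; their spacing along a parent tract is set by the tract-length
#' scale (~2.6 x the interbranch-distance target), which puts the median
#' interbranch distance (IBD) near its target. Both controlled statistics
#' are exactly bookkept on the generated polylines, which is what
#' parameter-recovery testing of the tracing pipeline needs. An optional
#' curly sub-mask gets its own multipliers (lower VLD, shorter IBD — the
#' remodeled-zone signature).
#'
#' @param mask Logical 3D array: tissue in which to grow the network.
#' @param geometry A [voxel_geometry()].
#' @param target_vld Target vessel length density, mm/mm³ (default 2900).
#' @param ibd_um Target median interbranch distance, µm (default 65).
#' @param curly_mask Optional logical sub-mask with altered statistics.
#' @param curly_vld_mult,curly_ibd_mult Multipliers applied inside the curly
#'   sub-mask (both < 1 for the remodeled-zone phenotype).
#' @param exclude_mask Optional mask (e.g. infarct void) kept free of vessels.
#' @param step_um Streamline integration step, µm.
#' @param margin_um Margin inside the mask kept free of centerlines, µm.
#' @param fiber Local fiber direction: a length-3 vector or a function
#'   mapping an n x 3 µm position matrix to direction rows; `NULL` uses an
#'   in-plane direction that rotates slowly along z.
#' @param jitter Direction noise per step (tortuosity; 0 = straight tracts).
#' @param tol Relative tolerance on the achieved total length (default 0.1).
#' @return A [vessel_graph()] with attribute `achieved_vld` (mm/mm³).
#' @export
generate_vessel_network <- function(mask, geometry, target_vld = 2900,
                                    ibd_um = 65, curly_mask = NULL,
                                    curly_vld_mult = 1771 / 2946,
                                    curly_ibd_mult = 51 / 67,
                                    exclude_mask = NULL,
                                    step_um = 5, margin_um = 6,
                                    fiber = NULL, jitter = 0.12, tol = 0.1) {
  sp <- voxel_spacing(geometry)
  if (!any(mask)) stop("mask is empty")
  if (target_vld < 0) stop("target VLD must be non-negative")
  empty_graph <- function() vessel_graph(matrix(numeric(), ncol = 3), list(),
                                         matrix(integer(), ncol = 2))
  if (target_vld == 0) {
    g <- empty_graph()
    attr(g, "achieved_vld") <- 0
    return(g)
  }
  # the placement margin applies at the outer tissue boundary only; vessels
  # run right up to an infarct border, so the exclusion zone is not eroded
  mask_inner <- binary_erode(mask, margin_um, voxel_spacing(geometry))
  if (!any(mask_inner)) mask_inner <- mask
  if (!is.null(exclude_mask)) {
    mask <- mask & !exclude_mask
    mask_inner <- mask_inner & !exclude_mask
  }
  base_mask <- if (is.null(curly_mask)) mask_inner else (mask_inner & !curly_mask)
  base_vol <- if (is.null(curly_mask)) mask else (mask & !curly_mask)
  if (is.null(fiber)) {
    extent_z <- dim(mask)[3] * sp[3]
    fiber <- function(p) {
      a <- 2 * pi * p[, 3] / max(4 * extent_z, 1)
      cbind(cos(a), sin(a), 0.2)
    }
  }

  # placement masks keep the boundary margin; the length budget is set by
  # the full tissue volume of each part
  parts <- list(list(mask = base_mask, vol_mask = base_vol,
                     vld = target_vld, ibd = ibd_um))
  if (!is.null(curly_mask) && any(curly_mask & mask)) {
    parts <- c(parts, list(list(mask = curly_mask & mask_inner,
                                vol_mask = curly_mask & mask,
                                vld = target_vld * curly_vld_mult,
                                ibd = ibd_um * curly_ibd_mult)))
  }

  all_nodes <- matrix(numeric(), ncol = 3)
  all_paths <- list()
  all_ends <- matrix(integer(), ncol = 2)
  region_lab <- integer()
  for (p in seq_along(parts)) {
    net <- grow_region_network(parts[[p]]$mask, sp, parts[[p]]$vld,
                               parts[[p]]$ibd, step_um, 0, fiber, jitter,
                               v_um3 = sum(parts[[p]]$vol_mask) * prod(sp))
    offset <- nrow(all_nodes)
    all_nodes <- rbind(all_nodes, net$nodes)
    all_paths <- c(all_paths, net$paths)
    if (nrow(net$ends)) all_ends <- rbind(all_ends, net$ends + offset)
    region_lab <- c(region_lab, rep(p, length(net$paths)))
  }
  if (!length(all_paths)) {
    g <- empty_graph()
    attr(g, "achieved_vld") <- 0
    return(g)
  }
  # granularity control: whole tracts can overshoot the length budget in
  # small domains; trim terminal segments until the total is on target
  v_mm3 <- sum(mask) * prod(sp) / UM3_PER_MM3
  eff_target_mm <- 0
  for (p in parts)
    eff_target_mm <- eff_target_mm + p$vld * sum(p$vol_mask) * prod(sp) / UM3_PER_MM3
  lens <- vapply(all_paths, polyline_length, numeric(1))
  keep_e <- rep(TRUE, length(all_paths))
  shorten_from_end <- function(e, cut_um) {
    # truncate the path at the 'to' side, freeing a new endpoint
    path <- all_paths[[e]]
    seg <- sqrt(rowSums(diff(path)^2))
    cum_rev <- rev(cumsum(rev(seg)))           # length remaining after row i
    keep_rows <- which(c(cum_rev, 0) >= cut_um)
    if (length(keep_rows) < 2) return(FALSE)
    path <- path[seq_len(max(keep_rows)), , drop = FALSE]
    all_paths[[e]] <<- path
    all_nodes <<- rbind(all_nodes, path[nrow(path), ])
    all_ends[e, 2] <<- nrow(all_nodes)
    lens[e] <<- polyline_length(path)
    TRUE
  }
  trim_iter <- 0
  repeat {
    trim_iter <- trim_iter + 1
    if (trim_iter > 300) break
    excess_um <- sum(lens[keep_e]) - 1000 * eff_target_mm
    if (excess_um <= 1000 * 0.03 * eff_target_mm) break
    deg <- tabulate(c(all_ends[keep_e, 1], all_ends[keep_e, 2]),
                    nbins = nrow(all_nodes))
    term <- which(keep_e & (deg[all_ends[, 1]] == 1 | deg[all_ends[, 2]] == 1))
    removable <- term[lens[term] <= excess_um]
    if (length(removable)) {
      keep_e[removable[which.max(lens[removable])]] <- FALSE
      next
    }
    # no whole edge fits the excess: shorten the longest candidate
    cand_t <- if (length(term)) term else which(keep_e)
    if (!length(cand_t)) break
    e <- cand_t[which.max(lens[cand_t])]
    if (length(term) && deg[all_ends[e, 2]] != 1) {
      # flip so the free end is the 'to' side
      all_paths[[e]] <- all_paths[[e]][rev(seq_len(nrow(all_paths[[e]]))), , drop = FALSE]
      all_ends[e, ] <- rev(all_ends[e, ])
    }
    if (!shorten_from_end(e, min(excess_um, lens[e] - 2 * step_um)))
      keep_e[e] <- FALSE
  }
  all_paths <- all_paths[keep_e]
  all_ends <- all_ends[keep_e, , drop = FALSE]
  region_lab <- region_lab[keep_e]
  used <- sort(unique(as.vector(all_ends)))
  remap <- integer(nrow(all_nodes)); remap[used] <- seq_along(used)
  all_nodes <- all_nodes[used, , drop = FALSE]
  all_ends <- cbind(remap[all_ends[, 1]], remap[all_ends[, 2]])

  g <- vessel_graph(all_nodes, all_paths, all_ends, provenance = "phantom-truth")
  g$edges$region <- c("base", "curly")[region_lab]

  achieved <- graph_total_length(g) / 1000 / v_mm3
  eff_target <- eff_target_mm / v_mm3
  if (abs(achieved - eff_target) / eff_target > tol)
    stop(sprintf("achieved VLD %.0f mm/mm3 misses target %.0f by more than %.0f%%",
                 achieved, eff_target, 100 * tol))
  attr(g, "achieved_vld") <- achieved
  g
}


# capillary-segment network for one homogeneous region: short tracts whose
# ends attach to neighbouring tracts (T-junctions), giving a connected mesh
# of interbranch segments without sub-resolution cross-links
grow_region_network <- function(mask, sp, vld, ibd, step_um, margin_um,
                                fiber, jitter, v_um3 = NULL) {
  empty <- list(nodes = matrix(numeric(), ncol = 3), paths = list(),
                ends = matrix(integer(), ncol = 2))
  if (!any(mask) || vld <= 0) return(empty)
  d <- dim(mask)
  if (is.null(v_um3)) v_um3 <- sum(mask) * prod(sp)
  vld_u <- vld * 1e-6                     # mm/mm3 -> µm/µm3
  s_t <- 1 / sqrt(vld_u)                  # mean capillary spacing
  l_target <- vld_u * v_um3
  # tract length scale and minimum junction spacing: attachments land where
  # tract ends happen to fall, so spacing along a parent is a hard minimum
  # plus a heavy tail; the scale is set so the overall interbranch median
  # lands near the IBD target
  l_tract_mean <- max(1.5 * ibd, min(2.6 * ibd, l_target / 10))
  min_junct_sep <- 0.5 * ibd

  inner <- binary_erode(mask, margin_um, sp)
  if (!any(inner)) inner <- mask
  fiber_fun <- if (is.function(fiber)) fiber else {
    fv <- fiber / sqrt(sum(fiber^2))
    function(p) matrix(fv, nrow(p), 3, byrow = TRUE)
  }
  inside <- function(pos) {
    i <- round(pos / sp) + 1
    all(i >= 1) && all(i <= d) && inner[i[1], i[2], i[3]]
  }

  # spatial hash of tract points: (x, y, z, tract id, row index)
  d_grow <- 0.5 * s_t
  d_seed <- 0.85 * s_t
  reach_att <- 1.6 * s_t
  cell <- s_t / 2
  occ_dim <- pmax(ceiling(d * sp / cell) + 1, 1)
  pts_hash <- vector("list", prod(occ_dim))
  cell_key <- function(pos) {
    k <- pmin(pmax(floor(pos / cell) + 1, 1), occ_dim)
    k[1] + occ_dim[1] * ((k[2] - 1) + occ_dim[2] * (k[3] - 1))
  }
  hash_query <- function(pos, tract_id, reach_cells) {
    k <- pmin(pmax(floor(pos / cell) + 1, 1), occ_dim)
    out <- NULL
    for (dz in -reach_cells:reach_cells)
      for (dy in -reach_cells:reach_cells)
        for (dx in -reach_cells:reach_cells) {
          kk <- k + c(dx, dy, dz)
          if (any(kk < 1) || any(kk > occ_dim)) next
          m <- pts_hash[[kk[1] + occ_dim[1] * ((kk[2] - 1) + occ_dim[2] * (kk[3] - 1))]]
          if (is.null(m)) next
          m <- m[m[, 4] != tract_id, , drop = FALSE]
          if (nrow(m)) out <- rbind(out, m)
        }
    out
  }
  # anisotropy-aware separation: axial (z) proximity is penalized because
  # 10 µm optical planes cannot resolve tracts stacked along z
  z_aniso <- 1
  near_dist <- function(pos, tract_id) {
    m <- hash_query(pos, tract_id, 2L)
    if (is.null(m)) return(Inf)
    sqrt(min((m[, 1] - pos[1])^2 + (m[, 2] - pos[2])^2 +
               ((m[, 3] - pos[3]) / z_aniso)^2))
  }
  push_pt <- function(pos, tract_id, idx) {
    key <- cell_key(pos)
    pts_hash[[key]] <<- rbind(pts_hash[[key]], c(pos, tract_id, idx))
  }

  # --- grow tracts (evenly spaced streamlines of bounded length) ---
  cand <- which(inner)
  cand <- cand[sample.int(length(cand))]
  tracts <- list()
  seed_queue <- list()
  total_len <- 0
  ci <- 0
  # end connectors (~1.8 tract spacings per tract on average) count towards
  # the length budget
  while (total_len + 1.8 * s_t * length(tracts) < l_target) {
    seed <- NULL
    while (length(seed_queue)) {
      s <- seed_queue[[1]]; seed_queue <- seed_queue[-1]
      if (inside(s) && near_dist(s, -1L) >= d_seed) { seed <- s; break }
    }
    if (is.null(seed)) {
      while (ci < length(cand)) {
        ci <- ci + 1
        s <- (arrayInd(cand[ci], d)[1, ] - 1) * sp
        if (near_dist(s, -1L) >= d_seed) { seed <- s; break }
      }
    }
    if (is.null(seed)) break
    tid <- length(tracts) + 1L
    l_max <- max(1.4 * ibd, rlnorm(1, log(l_tract_mean), 0.4))
    pieces <- list()
    for (sgn in c(1, -1)) {
      pos <- seed
      dir <- sgn * fiber_fun(matrix(seed, 1))[1, ]
      dir <- dir / max(sqrt(sum(dir^2)), 1e-12)
      pts <- matrix(seed, 1)
      len <- 0
      while (len < l_max / 2) {
        f <- sgn * fiber_fun(matrix(pos, 1))[1, ]
        f <- f / max(sqrt(sum(f^2)), 1e-12)
        dir <- 0.8 * dir + 0.2 * f + jitter * rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        nxt <- pos + step_um * dir
        if (!inside(nxt) || near_dist(nxt, tid) < d_grow) break
        pts <- rbind(pts, nxt)
        pos <- nxt
        len <- len + step_um
        if (len >= 1.3 * ibd &&
            total_len + len + 1.8 * s_t * length(tracts) >= l_target) break
      }
      pieces[[if (sgn == 1) 1 else 2]] <- pts
    }
    pl <- rbind(pieces[[2]][rev(seq_len(nrow(pieces[[2]]))), , drop = FALSE],
                pieces[[1]][-1, , drop = FALSE])
    if (nrow(pl) < 2 || polyline_length(pl) < 1.2 * ibd) next
    tracts[[tid]] <- pl
    total_len <- total_len + polyline_length(pl)
    for (r in seq_len(nrow(pl))) push_pt(pl[r, ], tid, r)
    # propose side seeds so neighbouring space fills evenly
    tangents <- path_tangents(pl)
    u <- perp_vector(tangents)
    v <- cross3(tangents, u)
    for (r in seq(1, nrow(pl), by = max(1, floor(s_t / step_um)))) {
      phi <- runif(2, 0, 2 * pi)
      for (q in 1:2)
        seed_queue[[length(seed_queue) + 1]] <-
          pl[r, ] + s_t * (cos(phi[q]) * u[r, ] + sin(phi[q]) * v[r, ])
    }
  }
  if (!length(tracts)) return(empty)
  n_t <- length(tracts)

  # --- attach tract ends to neighbouring tracts (T-junctions) ---
  reach_cells <- as.integer(ceiling(reach_att / cell))
  attach <- list()  # per attachment: child, child_end (1|2), parent, parent_idx
  pre_pts <- vector("list", n_t)   # connector points prepended to the child
  post_pts <- vector("list", n_t)
  junct_arc <- vector("list", n_t) # arc positions of junctions received so far
  for (t in seq_len(n_t)) {
    pl <- tracts[[t]]
    for (endside in 1:2) {
      pos <- if (endside == 1) pl[1, ] else pl[nrow(pl), ]
      m <- hash_query(pos, t, reach_cells)
      if (is.null(m)) next
      dd <- sqrt((m[, 1] - pos[1])^2 + (m[, 2] - pos[2])^2 + (m[, 3] - pos[3])^2)
      ord <- order(dd)
      ord <- ord[dd[ord] <= reach_att & dd[ord] > 1e-6]
      if (!length(ord)) next
      j <- NA_integer_
      for (jj in ord) {
        # keep junctions on the parent at least min_junct_sep apart
        p_arc <- m[jj, 5] * step_um
        prev <- junct_arc[[m[jj, 4]]]
        if (!is.null(prev) && any(abs(prev - p_arc) < min_junct_sep)) next
        j <- jj
        break
      }
      if (is.na(j)) next  # no admissible junction site; leave a free end
      target <- m[j, 1:3]
      n_sub <- max(1L, ceiling(dd[j] / step_um))
      conn <- outer(seq_len(n_sub) / n_sub, target - pos) +
        matrix(pos, n_sub, 3, byrow = TRUE)
      if (endside == 1) pre_pts[[t]] <- conn[rev(seq_len(n_sub)), , drop = FALSE]
      else post_pts[[t]] <- conn
      junct_arc[[m[j, 4]]] <- c(junct_arc[[m[j, 4]]], m[j, 5] * step_um)
      attach[[length(attach) + 1]] <-
        list(child = t, side = endside, parent = m[j, 4], pidx = m[j, 5])
    }
  }

  # --- assemble nodes and edges ---
  node_pos <- list(); node_id <- 0
  add_node <- function(p) {
    node_id <<- node_id + 1
    node_pos[[node_id]] <<- p
    node_id
  }
  # junction nodes at parent points
  junct <- list()  # per tract: data frame idx -> node
  for (t in seq_len(n_t)) junct[[t]] <- list(idx = integer(), node = integer())
  child_end_node <- matrix(NA_integer_, n_t, 2)
  for (a in attach) {
    p <- a$parent; i <- as.integer(a$pidx)
    hit <- which(junct[[p]]$idx == i)
    nd <- if (length(hit)) junct[[p]]$node[hit[1]] else {
      nd2 <- add_node(tracts[[p]][i, ])
      junct[[p]]$idx <- c(junct[[p]]$idx, i)
      junct[[p]]$node <- c(junct[[p]]$node, nd2)
      nd2
    }
    child_end_node[a$child, a$side] <- nd
  }

  paths <- list(); ends <- list()
  for (t in seq_len(n_t)) {
    pl <- tracts[[t]]
    npre <- if (is.null(pre_pts[[t]])) 0L else nrow(pre_pts[[t]])
    full <- rbind(pre_pts[[t]], pl, post_pts[[t]])
    cuts <- sort(unique(junct[[t]]$idx)) + npre
    cut_nodes <- junct[[t]]$node[order(junct[[t]]$idx)]
    start_node <- if (!is.na(child_end_node[t, 1])) child_end_node[t, 1] else add_node(full[1, ])
    end_node <- if (!is.na(child_end_node[t, 2])) child_end_node[t, 2] else add_node(full[nrow(full), ])
    b_idx <- c(1L, cuts, nrow(full))
    b_nodes <- c(start_node, cut_nodes, end_node)
    for (q in seq_len(length(b_idx) - 1)) {
      i0 <- b_idx[q]; i1 <- b_idx[q + 1]
      if (i1 <= i0) next
      paths[[length(paths) + 1]] <- full[i0:i1, , drop = FALSE]
      ends[[length(ends) + 1]] <- c(b_nodes[q], b_nodes[q + 1])
    }
  }
  list(nodes = do.call(rbind, node_pos), paths = paths,
       ends = do.call(rbind, ends))
}
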