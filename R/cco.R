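#' @keywords internal
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# Total intravascular volume of the tree after hypothetically splitting edge
# `i` at position `x` and attaching a new terminal to `Tpos`. Murray gamma-sums
# change only on the root path of `i`; everything else is precomputed in `pre`.
#' @keywords internal
.cco_insert_volume <- function(pre, i, x, Tpos) {
  g <- pre$gamma
  rlg <- pre$r_leaf^g
  P <- pre$nodes[pre$edges$parent[i], ]
  D <- pre$nodes[pre$edges$child[i], ]
  r2 <- function(rg) rg^(2 / g)
  vol <- pre$base_vol[i] # volume of all edges not on the root path of i, excl i
  # root path (excluding i): gamma-sums gain one leaf term
  for (j in pre$root_path[[i]]) {
    vol <- vol + pi * r2(pre$rg[j] + rlg) * pre$len[j]
  }
  lPx <- sqrt(sum((x - P)^2))
  lxD <- sqrt(sum((x - D)^2))
  lxT <- sqrt(sum((x - Tpos)^2))
  vol +
    pi * r2(pre$rg[i] + rlg) * lPx + # parent stem P -> x
    pi * r2(pre$rg[i]) * lxD + # continuation x -> D (old subtree)
    pi * r2(rlg) * lxT # new terminal x -> T
}

#' @keywords internal
.cco_precompute <- function(tree, r_leaf, gamma) {
  e <- tree$edges
  rg <- numeric(nrow(e))
  rg[tree$is_leaf] <- r_leaf^gamma
  for (i in rev(tree$topo)) {
    p <- tree$parent_edge[i]
    if (p > 0L) rg[p] <- rg[p] + rg[i]
  }
  root_path <- vector("list", nrow(e))
  for (i in seq_len(nrow(e))) {
    path <- integer()
    p <- tree$parent_edge[i]
    while (p > 0L) {
      path <- c(path, p)
      p <- tree$parent_edge[p]
    }
    root_path[[i]] <- path
  }
  vol_all <- pi * rg^(2 / gamma) * e$length
  total <- sum(vol_all)
  base_vol <- vapply(seq_len(nrow(e)), function(i) {
    total - vol_all[i] - sum(vol_all[root_path[[i]]])
  }, numeric(1))
  list(
    nodes = tree$nodes, edges = e, len = e$length, rg = rg,
    root_path = root_path, base_vol = base_vol,
    r_leaf = r_leaf, gamma = gamma
  )
}

#' Extend a vascular tree by constrained constructive optimization
#'
#' Grows the tree to `n_leaves_target` terminals. Each added terminal is a
#' new target site drawn uniformly from the mask foreground (with a
#' minimum-distance rejection rule) and connected through one new bifurcation
#' whose position minimizes the total intravascular volume
#' `sum(pi r^2 L)`, with radii recomputed from the Murray power law
#' (terminal radius `r_leaf`, exponent `gamma`) and equal terminal flows.
#' The bifurcation position is optimized by Nelder-Mead seeded at the
#' perpendicular foot point on the attachment edge, over the few nearest
#' candidate edges; positions whose new segment midpoints leave the mask
#' (beyond a one-voxel tolerance) are rejected. Deterministic for a fixed
#' seed.
#'
#' @param tree a [vascular_tree()] inside the mask.
#' @param mask an [organ_mask()].
#' @param n_leaves_target desired terminal count, `>=` current count.
#' @param seed integer RNG seed.
#' @param r_leaf terminal radius (mm).
#' @param gamma Murray exponent.
#' @param n_candidates number of nearest edges tried per insertion.
#' @param min_dist minimum distance of a new target site from existing nodes
#'   (mm); default scales with the per-leaf tissue volume.
#' @param min_seg_len minimum admissible length of the three segments a new
#'   bifurcation creates (mm); defaults to the mask spacing so that later
#'   pruning at the grid resolution cannot remove terminals.
#' @return the extended tree with Murray radii (flows re-assigned if the
#'   input tree had flows).
#' @export
cco_extend <- function(tree, mask, n_leaves_target, seed = 1L,
                       r_leaf = 0.15, gamma = 3, n_candidates = 3L,
                       min_dist = NULL, min_seg_len = mask$spacing) {
  n0 <- sum(tree$is_leaf)
  if (n_leaves_target < n0) stop("n_leaves_target below current leaf count")
  had_flow <- !is.null(tree$edges$flow)
  Q <- if (had_flow) sum(tree$edges$flow[tree$is_leaf]) else NULL
  if (n_leaves_target == n0) return(tree)
  if (is.null(min_dist))
    min_dist <- 0.5 * (mask$volume / n_leaves_target)^(1 / 3)
  centers <- mask_voxel_centers(mask)
  h <- mask$spacing
  targets <- matrix(numeric(0), 0, 3)
  tree <- .with_seed(seed, {
    for (add in seq_len(n_leaves_target - n0)) {
      pre <- .cco_precompute(tree, r_leaf, gamma)
      seg_d2 <- function(pts) {
        d2 <- rep(Inf, nrow(matrix(pts, ncol = 3)))
        for (i in seq_len(nrow(tree$edges))) {
          d2 <- pmin(d2, .point_segment_dist2(pts,
            tree$nodes[tree$edges$parent[i], ], tree$nodes[tree$edges$child[i], ]))
        }
        d2
      }
      best <- NULL
      dmin <- max(min_dist, 2 * min_seg_len)
      for (attempt in 1:40) {
        # draw a target site with minimum-distance rejection (relaxing slowly)
        Tpos <- NULL
        for (try in 1:30) {
          cand <- centers[sample.int(nrow(centers), 1L), ] +
            stats::runif(3, -h / 2, h / 2)
          if (seg_d2(cand) >= dmin^2) {
            Tpos <- cand
            break
          }
          if (try %% 10 == 0) dmin <- max(dmin * 0.8, 2 * min_seg_len)
        }
        if (is.null(Tpos)) next
        # candidate attachment edges: nearest by point-to-segment distance
        d2 <- vapply(seq_len(nrow(tree$edges)), function(i) {
          .point_segment_dist2(Tpos, tree$nodes[tree$edges$parent[i], ],
            tree$nodes[tree$edges$child[i], ])
        }, numeric(1))
        cand_edges <- order(d2)[seq_len(min(n_candidates, length(d2)))]
        in_ok <- function(x, P, D) {
          pts <- rbind(x, (P + x) / 2, (x + D) / 2, (x + Tpos) / 2)
          all(mask_contains(mask, pts, tol_voxels = 1L))
        }
        for (i in cand_edges) {
          P <- tree$nodes[tree$edges$parent[i], ]
          D <- tree$nodes[tree$edges$child[i], ]
          ab <- D - P
          t0 <- min(0.8, max(0.2, sum((Tpos - P) * ab) / sum(ab^2)))
          starts <- list((2 * (P + t0 * ab) + Tpos) / 3, P + t0 * ab,
            P + 0.5 * ab)
          obj <- function(x) {
            if (!in_ok(x, P, D)) return(1e30)
            if (sum((x - P)^2) < min_seg_len^2 ||
              sum((x - D)^2) < min_seg_len^2 ||
              sum((x - Tpos)^2) < min_seg_len^2) return(1e30)
            .cco_insert_volume(pre, i, x, Tpos)
          }
          x0 <- NULL
          for (s in starts) if (obj(s) < 1e30) { x0 <- s; break }
          if (is.null(x0)) next
          opt <- stats::optim(x0, obj, method = "Nelder-Mead",
            control = list(maxit = 200, reltol = 1e-8))
          if (is.null(best) || opt$value < best$value)
            best <- list(value = opt$value, x = opt$par, edge = i, T = Tpos)
        }
        if (!is.null(best)) break
      }
      if (is.null(best))
        stop(sprintf("CCO insertion %d: no admissible in-mask candidate site", add))
      Tpos <- best$T
      # realize the insertion: split edge, add bifurcation and terminal nodes
      i <- best$edge
      x <- best$x
      nn <- nrow(tree$nodes)
      nodes <- rbind(tree$nodes, x, Tpos)
      e <- tree$edges[, c("parent", "child", "radius")]
      oldD <- e$child[i]
      e$child[i] <- nn + 1L
      e <- rbind(e,
        data.frame(parent = nn + 1L, child = oldD, radius = 1),
        data.frame(parent = nn + 1L, child = nn + 2L, radius = 1))
      tree <- vascular_tree(tree$kind, nodes, e)
      tree <- murray_radii(tree, r_leaf, gamma)
      targets <- rbind(targets, Tpos)
    }
    tree
  })
  if (had_flow) tree <- assign_flows(tree, Q)
  attr(tree, "targets") <- targets
  tree
}

#' Baseline tree by nearest-segment attachment (no optimization)
#'
#' Connects the same sequence of target sites by attaching each directly to
#' the midpoint of the nearest existing edge, without optimizing the
#' bifurcation position. Used as the comparison baseline for the volume
#' optimality of [cco_extend()].
#'
#' @inheritParams cco_extend
#' @param targets optional matrix of target positions to connect (one row
#'   per added leaf, e.g. `attr(cco_tree, "targets")` for a like-for-like
#'   volume comparison); drawn randomly when `NULL`.
#' @export
nearest_attachment_extend <- function(tree, mask, n_leaves_target, seed = 1L,
                                      r_leaf = 0.15, gamma = 3,
                                      min_dist = NULL, targets = NULL) {
  n0 <- sum(tree$is_leaf)
  if (n_leaves_target <= n0) return(tree)
  if (is.null(min_dist))
    min_dist <- 0.5 * (mask$volume / n_leaves_target)^(1 / 3)
  centers <- mask_voxel_centers(mask)
  h <- mask$spacing
  .with_seed(seed, {
    for (add in seq_len(n_leaves_target - n0)) {
      Tpos <- NULL
      dmin <- min_dist
      if (!is.null(targets)) {
        Tpos <- targets[add, ]
      } else for (try in 1:60) {
        cand <- centers[sample.int(nrow(centers), 1L), ] +
          stats::runif(3, -h / 2, h / 2)
        if (min(sqrt(rowSums(sweep(tree$nodes, 2, cand)^2))) >= dmin) {
          Tpos <- cand
          break
        }
        if (try %% 20 == 0) dmin <- dmin * 0.7
      }
      if (is.null(Tpos)) stop("no admissible target site")
      d2 <- vapply(seq_len(nrow(tree$edges)), function(i) {
        .point_segment_dist2(Tpos, tree$nodes[tree$edges$parent[i], ],
          tree$nodes[tree$edges$child[i], ])
      }, numeric(1))
      i <- which.min(d2)
      P <- tree$nodes[tree$edges$parent[i], ]
      D <- tree$nodes[tree$edges$child[i], ]
      x <- (P + D) / 2
      nn <- nrow(tree$nodes)
      nodes <- rbind(tree$nodes, x, Tpos)
      e <- tree$edges[, c("parent", "child", "radius")]
      oldD <- e$child[i]
      e$child[i] <- nn + 1L
      e <- rbind(e,
        data.frame(parent = nn + 1L, child = oldD, radius = 1),
        data.frame(parent = nn + 1L, child = nn + 2L, radius = 1))
      tree <- vascular_tree(tree$kind, nodes, e)
      tree <- murray_radii(tree, r_leaf, gamma)
    }
    tree
  })
}
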