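# Hierarchical density-based clustering (HDBSCAN) over 3D point clouds:
# mutual-reachability minimum spanning tree (C++), condensed cluster tree,
# stability (excess-of-mass) selection with a split-stopping distance below
# which clusters are never divided.

#' Hierarchical density-based clustering
#'
#' @param pts N x 3 point matrix.
#' @param min_cluster_size smallest extractable cluster.
#' @param min_samples neighbour count defining the core distance.
#' @param eps_split split-stopping distance: clusters separating at a
#'   mutual-reachability distance below this are kept together.
#' @return integer vector of cluster labels (0 = noise).
#' @export
hdbscan_cluster <- function(pts, min_cluster_size, min_samples = 20,
                            eps_split = 0) {
  n <- nrow(pts)
  if (n < max(min_cluster_size, min_samples + 1)) return(rep(0L, n))
  kd <- cpp_knn_dist(pts, min_samples)
  core <- kd[, ncol(kd)]
  mst <- cpp_mreach_mst(pts, core)
  ord <- order(mst$weight)
  ef <- mst$from[ord]; et <- mst$to[ord]; ew <- mst$weight[ord]

  # single-linkage dendrogram over 2n-1 nodes
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  left <- integer(n - 1L); right <- integer(n - 1L); mdist <- numeric(n - 1L)
  size <- c(rep(1L, n), integer(n - 1L))
  uf_parent <- seq_len(n_nodes)
  uf_find <- function(i) {
    while (uf_parent[i] != i) {
      uf_parent[i] <<- uf_parent[uf_parent[i]]
      i <- uf_parent[i]
    }
    i
  }
  root_node <- integer(n_nodes)   # current dendrogram node of each uf root
  root_node[seq_len(n)] <- seq_len(n)
  for (k in seq_len(n - 1L)) {
    a <- uf_find(ef[k]); b <- uf_find(et[k])
    node <- n + k
    left[k] <- root_node[a]; right[k] <- root_node[b]; mdist[k] <- ew[k]
    size[node] <- size[root_node[a]] + size[root_node[b]]
    parent[root_node[a]] <- node; parent[root_node[b]] <- node
    uf_parent[a] <- b
    rb <- uf_find(b)
    root_node[rb] <- node
  }

  leaves_of <- function(node) {
    out <- integer(0); stack <- node
    while (length(stack) > 0) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (x <= n) out <- c(out, x)
      else {
        k <- x - n
        stack <- c(stack, left[k], right[k])
      }
    }
    out
  }

  # condensed tree
  m <- min_cluster_size
  max_cl <- 2L * n
  cl_parent <- integer(max_cl); cl_birth <- numeric(max_cl)
  cl_stab <- numeric(max_cl); cl_children <- vector("list", max_cl)
  cl_birth_dist <- numeric(max_cl)
  n_cl <- 1L
  cl_parent[1] <- 0L; cl_birth[1] <- 0; cl_birth_dist[1] <- Inf
  point_cl <- integer(n); point_lambda <- numeric(n)

  root <- n_nodes
  stack_node <- root; stack_cl <- 1L
  while (length(stack_node) > 0) {
    node <- stack_node[length(stack_node)]
    cl <- stack_cl[length(stack_cl)]
    stack_node <- stack_node[-length(stack_node)]
    stack_cl <- stack_cl[-length(stack_cl)]
    if (node <= n) {   # singleton continuation: point falls out immediately
      point_cl[node] <- cl
      point_lambda[node] <- Inf
      next
    }
    k <- node - n
    lam <- if (mdist[k] > 0) 1 / mdist[k] else Inf
    ch <- c(left[k], right[k])
    sz <- size[ch]
    if (all(sz >= m)) {
      # true split: two new condensed clusters
      cl_stab[cl] <- cl_stab[cl] + sum(sz) * (lam - cl_birth[cl])
      for (c2 in ch) {
        n_cl <- n_cl + 1L
        cl_parent[n_cl] <- cl
        cl_birth[n_cl] <- lam
        cl_birth_dist[n_cl] <- mdist[k]
        cl_children[[cl]] <- c(cl_children[[cl]], n_cl)
        stack_node <- c(stack_node, c2); stack_cl <- c(stack_cl, n_cl)
      }
    } else {
      for (i in 1:2) {
        if (sz[i] >= m) {
          stack_node <- c(stack_node, ch[i]); stack_cl <- c(stack_cl, cl)
        } else {
          lv <- leaves_of(ch[i])
          point_cl[lv] <- cl
          point_lambda[lv] <- lam
          cl_stab[cl] <- cl_stab[cl] + length(lv) * (lam - cl_birth[cl])
        }
      }
    }
  }

  if (n_cl == 1L) return(rep(0L, n))

  # excess-of-mass selection (root cluster never selectable)
  selected <- rep(FALSE, n_cl)
  subtree_stab <- cl_stab[seq_len(n_cl)]
  for (cl in seq(n_cl, 2L)) {
    kids <- cl_children[[cl]]
    if (length(kids) == 0) {
      selected[cl] <- TRUE
    } else if (cl_stab[cl] >= sum(subtree_stab[kids])) {
      selected[cl] <- TRUE
    } else {
      subtree_stab[cl] <- sum(subtree_stab[kids])
    }
  }
  # deselect descendants of selected clusters (top-down)
  for (cl in seq(2L, n_cl)) {
    p <- cl_parent[cl]
    while (p > 1L) {
      if (selected[p]) { selected[cl] <- FALSE; break }
      p <- cl_parent[p]
    }
  }
  # split-stopping distance: clusters born from a split closer than
  # eps_split merge upward
  if (eps_split > 0) {
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (cl in which(selected)) {
        if (cl_birth_dist[cl] < eps_split && cl_parent[cl] > 1L) {
          p <- cl_parent[cl]
          while (cl_parent[p] > 1L && cl_birth_dist[p] < eps_split)
            p <- cl_parent[p]
          # select ancestor, deselect its subtree
          sub <- p
          frontier <- cl_children[[p]]
          while (length(frontier) > 0) {
            sub <- c(sub, frontier)
            frontier <- unlist(cl_children[frontier])
          }
          selected[sub] <- FALSE
          selected[p] <- TRUE
          changed <- TRUE
          break
        }
      }
    }
  }

  # labels: deepest selected ancestor of each point's condensed cluster
  sel_ids <- which(selected)
  lab_of_cl <- integer(n_cl)
  lab_of_cl[sel_ids] <- seq_along(sel_ids)
  labels <- integer(n)
  for (p in seq_len(n)) {
    cl <- point_cl[p]
    while (cl > 0L && !selected[cl]) cl <- cl_parent[cl]
    labels[p] <- if (cl > 0L) lab_of_cl[cl] else 0L
  }
  labels
}
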