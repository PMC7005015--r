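# Independent reference implementations used as oracles. These deliberately
# recompute everything from scratch (exhaustive scans, enumeration, closed
# forms) and share no code with the package internals they check.

# ---- brute-force I-DT: windowed exhaustive scan ------------------------------

oracle_idt_run <- function(t, xd, yd, min_dur, max_disp, metric = "max") {
  eps <- 1e-9
  disp <- function(a, b) {
    dx <- max(xd[a:b]) - min(xd[a:b])
    dy <- max(yd[a:b]) - min(yd[a:b])
    if (metric == "sum") dx + dy else max(dx, dy)
  }
  n <- length(t)
  out <- NULL
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && t[j] - t[i] < min_dur - eps) j <- j + 1
    if (t[j] - t[i] < min_dur - eps) break
    if (disp(i, j) <= max_disp + eps) {
      while (j < n && disp(i, j + 1) <= max_disp + eps) j <- j + 1
      out <- rbind(out, c(i, j))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# full detector reference: split on invalid samples, scan each run, return
# (t_start, t_end) intervals
oracle_detect <- function(samples, config) {
  s <- config$scene_fov_deg / config$scene_resolution_px
  valid <- as.logical(samples$valid)
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  res <- NULL
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    idx <- starts[k]:ends[k]
    w <- oracle_idt_run(samples$t[idx], samples$x[idx] * s[1],
                        samples$y[idx] * s[2],
                        config$min_fixation_ms, config$max_dispersion_deg,
                        config$dispersion_metric)
    if (!is.null(w)) {
      res <- rbind(res, cbind(samples$t[idx[w[, 1]]], samples$t[idx[w[, 2]]]))
    }
  }
  res
}

# ---- flood-fill connected components (recursive stack DFS) -------------------

oracle_components <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    as.matrix(expand.grid(dr = -1:1, dc = -1:1)[-5, ])
  }
  cur <- 0L
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (!mask[rr, cc] || lab[rr, cc] > 0) next
    cur <- cur + 1L
    stack <- list(c(rr, cc))
    lab[rr, cc] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (d in seq_len(nrow(nb))) {
        r2 <- p[1] + nb[d, 1]; c2 <- p[2] + nb[d, 2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            mask[r2, c2] && lab[r2, c2] == 0) {
          lab[r2, c2] <- cur
          stack[[length(stack) + 1]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# compare two labelings as partitions (label ids may differ)
same_partition <- function(lab1, lab2) {
  f <- function(lab) {
    comps <- split(which(lab != 0), lab[lab != 0])
    sort(vapply(comps, function(ix) paste(sort(ix), collapse = ","), character(1)))
  }
  identical(unname(f(lab1)), unname(f(lab2)))
}

# ---- hand sums-of-squares mixed 2x2x2 ANOVA (balanced designs) ---------------

oracle_mixed_anova <- function(d) {
  # d: participant, group, speech, task, y; balanced, complete
  ms <- function(...) tapply(d$y, lapply(list(...), function(v) d[[v]]), mean)
  m <- mean(d$y)
  n <- length(unique(d$participant[d$group == unique(d$group)[1]]))
  N <- 2 * n
  y_g <- ms("group"); y_s <- ms("speech"); y_t <- ms("task")
  y_i <- tapply(d$y, d$participant, mean)
  grp_of <- tapply(d$group, d$participant, function(v) v[1])
  y_gs <- ms("group", "speech"); y_gt <- ms("group", "task")
  y_st <- ms("speech", "task"); y_gst <- ms("group", "speech", "task")
  y_is <- tapply(d$y, list(d$participant, d$speech), mean)
  y_it <- tapply(d$y, list(d$participant, d$task), mean)

  SS_G <- 4 * n * sum((y_g - m)^2)
  SS_BSerr <- 4 * sum((y_i - y_g[grp_of[names(y_i)]])^2)
  SS_S <- 4 * n * sum((y_s - m)^2)
  SS_SG <- 2 * n * sum((sweep(sweep(y_gs, 1, y_g), 2, y_s) + m)^2)
  SS_Serr <- 2 * sum((y_is - outer(y_i, rep(1, 2)) -
                        y_gs[grp_of[rownames(y_is)], ] +
                        outer(y_g[grp_of[rownames(y_is)]], rep(1, 2)))^2)
  SS_T <- 4 * n * sum((y_t - m)^2)
  SS_TG <- 2 * n * sum((sweep(sweep(y_gt, 1, y_g), 2, y_t) + m)^2)
  SS_Terr <- 2 * sum((y_it - outer(y_i, rep(1, 2)) -
                        y_gt[grp_of[rownames(y_it)], ] +
                        outer(y_g[grp_of[rownames(y_it)]], rep(1, 2)))^2)
  SS_ST <- 2 * n * sum((sweep(sweep(y_st, 1, y_s), 2, y_t) + m)^2)
  ST_int <- y_gst
  for (g in dimnames(y_gst)[[1]]) for (s in dimnames(y_gst)[[2]])
    for (tk in dimnames(y_gst)[[3]]) {
      ST_int[g, s, tk] <- y_gst[g, s, tk] - y_gs[g, s] - y_gt[g, tk] -
        y_st[s, tk] + y_g[g] + y_s[s] + y_t[tk] - m
    }
  SS_STG <- n * sum(ST_int^2)
  SS_tot <- sum((d$y - m)^2)
  SS_STerr <- SS_tot - SS_G - SS_BSerr - SS_S - SS_SG - SS_Serr -
    SS_T - SS_TG - SS_Terr - SS_ST - SS_STG
  dfe <- N - 2
  F_of <- function(ss, sse) (ss / 1) / (sse / dfe)
  list(
    Group = F_of(SS_G, SS_BSerr),
    Speech = F_of(SS_S, SS_Serr),
    `Speech:Group` = F_of(SS_SG, SS_Serr),
    Task = F_of(SS_T, SS_Terr),
    `Task:Group` = F_of(SS_TG, SS_Terr),
    `Speech:Task` = F_of(SS_ST, SS_STerr),
    `Speech:Task:Group` = F_of(SS_STG, SS_STerr)
  )
}

# ---- enumeration oracles for the rank tests ----------------------------------

oracle_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wall <- as.vector(signs %*% rk)
  p <- min(1, 2 * min(mean(Wall <= W + 1e-9), mean(Wall >= W - 1e-9)))
  list(V = W, p = p)
}

oracle_mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  rk <- rank(c(x, y))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- combn(n1 + n2, n1)
  Uall <- colSums(matrix(rk[splits], nrow = n1)) - n1 * (n1 + 1) / 2
  p <- min(1, 2 * min(mean(Uall <= U + 1e-9), mean(Uall >= U - 1e-9)))
  list(U = U, p = p)
}

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  rhos <- vapply(all_perms(ry), function(p) cor(rx, p), numeric(1))
  list(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-9))
}

# ---- geometry helpers --------------------------------------------------------

# ray-casting point-in-polygon (boundary treated as inside via epsilon pushes)
oracle_in_quad <- function(px, py, box) {
  xs <- box[, 1]; ys <- box[, 2]
  n <- 4
  inside <- FALSE
  j <- n
  for (i in 1:n) {
    # on-edge check first
    ax <- xs[j]; ay <- ys[j]; bx <- xs[i]; by <- ys[i]
    cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
    dot <- (px - ax) * (bx - ax) + (py - ay) * (by - ay)
    len2 <- (bx - ax)^2 + (by - ay)^2
    if (abs(cross) < 1e-9 * sqrt(len2 + 1) && dot >= -1e-9 && dot <= len2 + 1e-9) {
      return(TRUE)
    }
    if ((ys[i] > py) != (ys[j] > py)) {
      xint <- (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i]
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_classify <- function(px, py, box) {
  if (!oracle_in_quad(px, py, box)) return("outside")
  l <- (box[1, ] + box[4, ]) / 2
  r <- (box[2, ] + box[3, ]) / 2
  s <- (r[1] - l[1]) * (py - l[2]) - (r[2] - l[2]) * (px - l[1])
  s_top <- (r[1] - l[1]) * (box[1, 2] - l[2]) - (r[2] - l[2]) * (box[1, 1] - l[1])
  if (s == 0 || sign(s) == sign(s_top)) "upper" else "lower"
}

# random convex quadrilateral (TL, TR, BR, BL) by perturbing a rectangle
random_convex_quad <- function(cx = 640, cy = 480, hw = 120, hh = 150,
                               wobble = 30) {
  repeat {
    box <- rbind(
      c(cx - hw + runif(1, -wobble, wobble), cy - hh + runif(1, -wobble, wobble)),
      c(cx + hw + runif(1, -wobble, wobble), cy - hh + runif(1, -wobble, wobble)),
      c(cx + hw + runif(1, -wobble, wobble), cy + hh + runif(1, -wobble, wobble)),
      c(cx - hw + runif(1, -wobble, wobble), cy + hh + runif(1, -wobble, wobble))
    )
    ok <- tryCatch({
      dyadscan:::check_box(box)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(box)
  }
}

# forward bilinear map used to check the package inverse
oracle_forward_bilinear <- function(u, v, box) {
  c((1 - u) * (1 - v) * box[1, 1] + u * (1 - v) * box[2, 1] +
      u * v * box[3, 1] + (1 - u) * v * box[4, 1],
    (1 - u) * (1 - v) * box[1, 2] + u * (1 - v) * box[2, 2] +
      u * v * box[3, 2] + (1 - u) * v * box[4, 2])
}
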