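# Independent oracles and random-input generators.
#
# oracle_match_rule() re-derives rule matches by brute force: for every
# anchor it scans every admissible (anchor, end) pair, recomputing each
# condition's satisfying frame with explicit frame-by-frame loops and
# evaluating the Boolean tree per end frame, under the same semantics as the
# production matcher (strict windows, exclusion boundaries, not-tracked
# joints unsatisfiable, refractory consumption of immediately re-firing
# anchors, interval reported from earliest satisfying frame to the frame
# where the expression became true).

oracle_series <- function(stream, cond) {
  jm <- function(col) matrix(stream[[col]], nrow = 20)
  j <- match(cond$joint, fmsdetect::skeleton_joints())
  st <- jm("state")
  if (cond$kind == "disp") {
    list(series = jm(cond$axis)[j, ], valid = st[j, ] != "not_tracked")
  } else {
    parent <- fmsdetect::joint_parent()[[cond$joint]]
    child <- fmsdetect::joint_first_child()[[cond$joint]]
    n <- ncol(st)
    if (is.na(parent) || is.na(child)) {
      return(list(series = rep(NA_real_, n), valid = rep(FALSE, n)))
    }
    jp <- match(parent, fmsdetect::skeleton_joints())
    jc <- match(child, fmsdetect::skeleton_joints())
    ang <- numeric(n); ok <- logical(n)
    for (f in seq_len(n)) {
      p <- c(jm("x")[j, f], jm("y")[j, f], jm("z")[j, f])
      u <- c(jm("x")[jp, f], jm("y")[jp, f], jm("z")[jp, f]) - p
      v <- c(jm("x")[jc, f], jm("y")[jc, f], jm("z")[jc, f]) - p
      cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
      ok[f] <- is.finite(cosang) &&
        all(st[c(j, jp, jc), f] != "not_tracked")
      ang[f] <- acos(min(1, max(-1, cosang))) * 180 / pi
    }
    list(series = ang, valid = ok)
  }
}

oracle_cmp <- function(d, cmp, thr) {
  if (cmp == "abs_ge") return(abs(d) >= thr)
  if (cmp == "signed_ge") return(d >= thr)
  d <= thr
}

oracle_leaves <- function(expr) {
  if (inherits(expr, "fms_condition")) return(list(expr))
  unlist(lapply(expr$children, oracle_leaves), recursive = FALSE)
}

oracle_match_rule <- function(stream, rule) {
  n <- nrow(stream) / 20
  t <- matrix(stream$time, nrow = 20)[1, ]
  excl <- matrix(stream$excluded, nrow = 20)[1, ]
  leaves <- oracle_leaves(rule$expr)
  preps <- lapply(leaves, function(l) oracle_series(stream, l))
  w_max <- max(sapply(leaves, function(l) l$window_s))

  # admissible window frames from anchor i (ascending)
  window_of <- function(i) {
    js <- integer(0)
    j <- i + 1L
    while (j <= n && !excl[j] && t[j] - t[i] < w_max) {
      js <- c(js, j)
      j <- j + 1L
    }
    js
  }

  # first satisfying frame of leaf l at anchor i, or Inf
  leaf_sat <- function(l, prep, i, js) {
    if (!prep$valid[i]) return(Inf)
    for (j in js) {
      if (t[j] - t[i] >= l$window_s) next
      if (!prep$valid[j]) next
      if (oracle_cmp(prep$series[j] - prep$series[i], l$cmp, l$threshold)) {
        return(j)
      }
    }
    Inf
  }

  # per-end-frame truth of a node given the per-leaf satisfying frames;
  # returns a logical vector aligned with js
  node_truth <- function(expr, js, sats, counter) {
    if (inherits(expr, "fms_condition")) {
      s <- sats[counter$i]; counter$i <- counter$i + 1L
      return(js >= s)
    }
    kid_vecs <- lapply(expr$children, node_truth, js = js, sats = sats,
                       counter = counter)
    if (expr$op == "and") {
      out <- rep(TRUE, length(js))
      for (v in kid_vecs) out <- out & v
      return(out)
    }
    if (expr$op == "or") {
      out <- rep(FALSE, length(js))
      for (v in kid_vecs) out <- out | v
      return(out)
    }
    av <- kid_vecs[[1]]; cv <- kid_vecs[[2]]
    if (!any(av)) return(rep(TRUE, length(js)))
    afirst <- js[which(av)[1]]
    ok_c <- which(cv & js >= afirst)
    out <- js < afirst
    if (length(ok_c) > 0) out <- out | js >= js[ok_c[1]]
    out
  }

  try_anchor <- function(i) {
    js <- window_of(i)
    if (length(js) == 0) return(NULL)
    sats <- mapply(function(l, p) leaf_sat(l, p, i, js), leaves, preps)
    if (all(!is.finite(sats))) return(NULL)
    counter <- new.env(); counter$i <- 1L
    truth <- node_truth(rule$expr, js, sats, counter)
    ok <- truth & (js >= min(sats))
    if (!any(ok)) return(NULL)
    end <- js[which(ok)[1]]
    list(start = min(sats[sats <= end]), end = end)
  }

  starts <- ends <- anchors <- integer(0)
  i <- 1L
  suppress <- FALSE
  while (i <= n) {
    if (excl[i]) {
      suppress <- FALSE; i <- i + 1L; next
    }
    res <- try_anchor(i)
    if (!is.null(res)) {
      if (!suppress) {
        starts <- c(starts, res$start); ends <- c(ends, res$end)
        anchors <- c(anchors, i)
        suppress <- TRUE
        i <- res$end
      } else {
        i <- i + 1L
      }
    } else {
      suppress <- FALSE; i <- i + 1L
    }
  }
  data.frame(start_frame = as.integer(starts), end_frame = as.integer(ends),
             anchor_frame = as.integer(anchors))
}

# ---- random inputs ----------------------------------------------------------

# random-walk stream with occasional dropouts and exclusions
random_stream <- function(n_frames, seed, p_dropout = 0.3, p_exclusion = 0.3,
                          step_sd = 0.02) {
  set.seed(seed)
  t <- (0:(n_frames - 1)) / 30
  walk <- function() apply(matrix(rnorm(n_frames * 20, 0, step_sd),
                                  n_frames, 20), 2, cumsum)
  xm <- 0.0 + walk(); ym <- 1.0 + walk(); zm <- 2.5 + walk()
  if (n_frames == 1) {
    xm <- matrix(xm, 1); ym <- matrix(ym, 1); zm <- matrix(zm, 1)
  }
  state <- matrix("tracked", n_frames, 20)
  if (runif(1) < p_dropout) {
    for (k in 1:sample(1:3, 1)) {
      j <- sample(1:20, 1)
      a <- sample(1:n_frames, 1)
      b <- min(n_frames, a + sample(1:10, 1))
      state[a:b, j] <- sample(c("inferred", "not_tracked"), 1)
    }
  }
  excl <- NULL
  if (runif(1) < p_exclusion && n_frames > 10) {
    a <- runif(1, 0, t[n_frames] * 0.8)
    excl <- data.frame(start_s = a, end_s = a + runif(1, 0.1, 0.5))
  }
  stream <- fmsdetect:::stream_from_matrices(t, xm, ym, zm, state, rate = 30)
  if (!is.null(excl)) stream <- apply_exclusions(stream, excl)
  stream
}

random_condition <- function() {
  if (runif(1) < 0.12) {
    joint <- sample(c("spine", "shoulder_centre", "elbow_left", "knee_right",
                      "ankle_left", "wrist_right"), 1)
    angle_condition(joint, sample(c("abs_ge", "signed_ge", "signed_le"), 1),
                    round(runif(1, 1, 30), 1), sample(c(0.3, 0.5, 1.0), 1))
  } else {
    disp_condition(
      sample(skeleton_joints(), 1), sample(c("x", "y", "z"), 1),
      sample(c("abs_ge", "abs_ge", "signed_ge", "signed_le"), 1),
      round(runif(1, 0.02, 0.18), 3) *
        (if (runif(1) < 0.25) -1 else 1),
      sample(c(0.2, 0.3, 0.5, 1.0), 1)
    )
  }
}

random_rule <- function(seed, allow_then = TRUE) {
  set.seed(seed)
  n_leaves <- sample(1:4, 1)
  leaves <- replicate(n_leaves, random_condition(), simplify = FALSE)
  expr <- if (n_leaves == 1) {
    leaves[[1]]
  } else {
    shape <- sample(c("and", "or", "mixed", if (allow_then) "then"), 1)
    if (shape == "and") do.call(rule_and, leaves)
    else if (shape == "or") do.call(rule_or, leaves)
    else if (shape == "then") {
      rest <- if (n_leaves == 2) leaves[[2]] else do.call(rule_and, leaves[-1])
      rule_then(leaves[[1]], rest)
    } else {
      half <- ceiling(n_leaves / 2)
      left <- if (half == 1) leaves[[1]] else do.call(rule_and, leaves[1:half])
      right <- if (n_leaves - half == 1) leaves[[n_leaves]]
               else do.call(rule_and, leaves[(half + 1):n_leaves])
      rule_or(left, right)
    }
  }
  movement_rule(paste0("R", seed), expr)
}

# ---- independent ICC(2,1) oracle -------------------------------------------

# mean squares via stats::aov on the long layout, then the published
# absolute-agreement single-measures formula
oracle_icc21 <- function(a, b) {
  n <- length(a); k <- 2
  long <- data.frame(
    y = c(a, b),
    subj = factor(rep(seq_len(n), 2)),
    rater = factor(rep(c("a", "b"), each = n))
  )
  tab <- summary(stats::aov(y ~ subj + rater, data = long))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

random_count_table <- function(seed, n = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(4:30, 1)
  base <- rpois(n, sample(3:25, 1))
  a <- base + rpois(n, 2)
  b <- base + rpois(n, 2)
  tibble::tibble(participant = seq_len(n), a = a, b = b)
}
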