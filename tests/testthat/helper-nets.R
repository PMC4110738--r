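# shared fixtures and oracles for the test suite

.cache <- new.env(parent = emptyenv())

# the packaged pathway model, built once per test run
test_model <- function() {
  if (is.null(.cache$model)) .cache$model <- build_pathway_model()
  .cache$model
}

# a network_config over the pathway with every randomized weight equal to
# `fill`, with optional overrides, carrying the model's presence marking
uniform_config <- function(fill = 1L, overrides = NULL) {
  model <- test_model()
  ids <- edge_ids(model$net)[!model$net$arcs$read]
  w <- setNames(rep(as.integer(fill), length(ids)), ids)
  if (!is.null(overrides)) w[names(overrides)] <- as.integer(overrides)
  config <- set_weights(model$net, w)
  config$m0 <- marking(model$net, model$m0[as.integer(model$m0) > 0L])
  config
}

# random small net: places p1..pn, transitions t1..tn, arc weights <= wmax,
# optional read arcs
random_small_net <- function(n_places = sample(3:6, 1),
                             n_trans = sample(2:6, 1),
                             wmax = 3, p_read = 0.15, tokens_max = 4) {
  pl <- paste0("p", seq_len(n_places))
  tr <- paste0("t", seq_len(n_trans))
  arcs <- NULL
  for (t in tr) {
    pre <- sample(pl, sample(0:2, 1))
    post <- sample(pl, sample(0:2, 1))
    if (length(pre) > 0L)
      arcs <- rbind(arcs, data.frame(
        src = pre, dst = t, weight = sample(seq_len(wmax), length(pre),
                                            replace = TRUE),
        read = runif(length(pre)) < p_read))
    if (length(post) > 0L)
      arcs <- rbind(arcs, data.frame(
        src = t, dst = post, weight = sample(seq_len(wmax), length(post),
                                             replace = TRUE), read = FALSE))
  }
  if (is.null(arcs)) arcs <- data.frame(src = pl[1], dst = tr[1],
                                        weight = 1L, read = FALSE)
  arcs <- arcs[!duplicated(arcs[, c("src", "dst")]), , drop = FALSE]
  arcs$weight[arcs$read] <- 1L
  # a read arc (q, t) coexisting with a product arc (t, q) would make q's
  # count change on firing t; keep read-arc neutrality well-posed by
  # dropping such product arcs
  read_pairs <- paste(arcs$src[arcs$read], arcs$dst[arcs$read])
  arcs <- arcs[!(paste(arcs$dst, arcs$src) %in% read_pairs), , drop = FALSE]
  net <- petri_net(pl, tr, arcs)
  m0 <- marking(net, setNames(sample(0:tokens_max, n_places, replace = TRUE),
                              pl))
  list(net = net, m0 = m0)
}

# Exhaustive-interleaving reachability oracle: breadth-first search over all
# firing orders (with the fire-once rule for source transitions), asking
# whether any schedule of <= depth firings fires `target`.  Returns TRUE /
# FALSE, or NA when the search was truncated by the state or depth caps.
bfs_target_reachable <- function(net, m0, target, depth = 25L,
                                 max_states = 40000L) {
  trans <- net$transitions
  pre <- lapply(trans, function(t) pre_arcs(net, t))
  names(pre) <- trans
  is_src <- vapply(pre, function(p) nrow(p) == 0L, logical(1))
  key <- function(m, dead) paste(paste(m, collapse = ","),
                                 paste(as.integer(dead), collapse = ""))
  start_dead <- setNames(logical(length(trans)), trans)
  frontier <- list(list(m = as.integer(m0[net$places]), dead = start_dead))
  seen <- new.env(parent = emptyenv())
  assign(key(frontier[[1]]$m, start_dead), TRUE, envir = seen)
  truncated <- FALSE
  for (d in seq_len(depth)) {
    nxt <- list()
    for (st in frontier) {
      m <- setNames(st$m, net$places)
      for (t in trans) {
        if (st$dead[t]) next
        p <- pre[[t]]
        if (nrow(p) > 0L && !all(m[p$src] >= p$weight)) next
        if (t == target) return(TRUE)
        m2 <- m
        ord <- p[!p$read, , drop = FALSE]
        if (nrow(ord) > 0L) m2[ord$src] <- m2[ord$src] - ord$weight
        post <- net$arcs[net$arcs$src == t, , drop = FALSE]
        if (nrow(post) > 0L)
          for (i in seq_len(nrow(post)))
            m2[post$dst[i]] <- m2[post$dst[i]] + post$weight[i]
        dead2 <- st$dead
        if (is_src[t]) dead2[t] <- TRUE
        k <- key(as.integer(m2), dead2)
        if (!exists(k, envir = seen)) {
          assign(k, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- list(m = as.integer(m2), dead = dead2)
        }
      }
      if (length(seen) > max_states) { truncated <- TRUE; break }
    }
    if (truncated) break
    if (length(nxt) == 0L) return(FALSE)
    frontier <- nxt
  }
  NA
}

# planted-signal dataset: class determined by one attribute's threshold,
# all other attributes pure noise; `gap` excludes planted values within
# gap of the cutoff so every reasonable split separates the classes
planted_dataset <- function(n = 120, n_attr = 8, planted = "s2TOt2",
                            cutoff = 50, seed = 1, noise = 0, gap = 0L) {
  set.seed(seed)
  attrs <- c(planted, sprintf("edge%02d", seq_len(n_attr - 1L)))
  df <- as.data.frame(setNames(
    lapply(attrs, function(a) sample.int(100L, n, replace = TRUE)), attrs))
  if (gap > 0L) {
    banned <- df[[planted]] > cutoff - gap & df[[planted]] <= cutoff + gap
    df[[planted]][banned] <- ifelse(df[[planted]][banned] <= cutoff,
                                    cutoff - gap, cutoff + gap + 1L)
  }
  lab <- ifelse(df[[planted]] <= cutoff, "P", "N")
  if (noise > 0) {
    flip <- sample.int(n, round(noise * n))
    lab[flip] <- ifelse(lab[flip] == "P", "N", "P")
  }
  df$class <- factor(lab, levels = c("P", "N"))
  df
}

# exhaustive single-split oracle: the (attribute, threshold) minimizing
# misclassification over all single binary splits
best_single_split <- function(df) {
  attrs <- setdiff(names(df), "class")
  best <- list(err = Inf)
  for (a in attrs) {
    xs <- sort(unique(df[[a]]))
    for (cut in xs) {
      left <- df$class[df[[a]] <= cut]
      right <- df$class[df[[a]] > cut]
      for (lab in levels(df$class)) {
        err <- sum(left != lab) + sum(right == lab)
        if (err < best$err)
          best <- list(attr = a, cut = cut, err = err)
      }
    }
  }
  best
}
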