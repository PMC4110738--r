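#' Construct a Petri net
#'
#' A Petri net is a weighted directed bipartite graph over disjoint sets of
#' places (species/conditions) and transitions (reactions/events).  Arcs run
#' only between a place and a transition.  A read arc (regulatory edge) is a
#' logically bidirectional weight-1 connection recorded once with the place
#' as source: the transition needs at least one token in the place to fire,
#' but firing does not change the place's token count.
#'
#' @param places character vector of place identifiers.
#' @param transitions character vector of transition identifiers (disjoint
#'   from `places`).
#' @param arcs data frame with columns `src`, `dst`, `weight` (positive
#'   integer) and optionally `read` (logical, default `FALSE`).  Read arcs
#'   must have `src` a place, `dst` a transition and weight 1.
#' @param labels optional named character vector of human-readable node
#'   labels.
#' @param place_tags,transition_tags optional named lists of character tag
#'   vectors (e.g. `"pool"`, `"psi"`, `"ste"`) attached to nodes.
#' @return an object of class `petri_net`.
#' @examples
#' net <- petri_net(c("p1", "p2"), "t1",
#'                  data.frame(src = c("p1", "t1"), dst = c("t1", "p2"),
#'                             weight = c(2L, 1L)))
#' @export
petri_net <- function(places, transitions, arcs, labels = NULL,
                      place_tags = NULL, transition_tags = NULL) {
  places <- as.character(places)
  transitions <- as.character(transitions)
  if (anyDuplicated(places)) stop("duplicated place identifiers")
  if (anyDuplicated(transitions)) stop("duplicated transition identifiers")
  if (length(intersect(places, transitions)) > 0L)
    stop("places and transitions must be disjoint sets: ",
         paste(intersect(places, transitions), collapse = ", "))
  arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)
  if (is.null(arcs$read)) arcs$read <- FALSE
  arcs <- arcs[, c("src", "dst", "weight", "read")]
  arcs$src <- as.character(arcs$src)
  arcs$dst <- as.character(arcs$dst)
  arcs$weight <- as.integer(arcs$weight)
  arcs$read <- as.logical(arcs$read)
  if (nrow(arcs) > 0L) {
    src_p <- arcs$src %in% places
    dst_p <- arcs$dst %in% places
    src_t <- arcs$src %in% transitions
    dst_t <- arcs$dst %in% transitions
    bad <- !((src_p & dst_t) | (src_t & dst_p))
    if (any(bad))
      stop("arcs must connect a place and a transition: ",
           paste(arcs$src[bad], "->", arcs$dst[bad], collapse = "; "))
    if (any(arcs$weight < 1L) || anyNA(arcs$weight))
      stop("all arc weights must be integers >= 1")
    if (any(arcs$read & !(src_p & dst_t)))
      stop("read arcs must be recorded place -> transition")
    if (any(arcs$read & arcs$weight != 1L))
      stop("read arcs must have weight 1")
    if (anyDuplicated(arcs[, c("src", "dst", "read")]))
      stop("duplicated arcs")
  }
  structure(
    list(places = places, transitions = transitions, arcs = arcs,
         labels = labels, place_tags = place_tags,
         transition_tags = transition_tags),
    class = "petri_net")
}

#' @export
print.petri_net <- function(x, ...) {
  cat(sprintf("<petri_net> %d places, %d transitions, %d arcs (%d read)\n",
              length(x$places), length(x$transitions), nrow(x$arcs),
              sum(x$arcs$read)))
  invisible(x)
}

#' Construct a marking
#'
#' A marking assigns a non-negative integer token count to every place of a
#' net.  Places not mentioned in `tokens` are set to zero.
#'
#' @param net a [petri_net].
#' @param tokens named integer vector of token counts for a subset of places.
#' @return named integer vector over all places of `net`, class `marking`.
#' @export
marking <- function(net, tokens = integer()) {
  m <- setNames(integer(length(net$places)), net$places)
  if (length(tokens) > 0L) {
    unknown <- setdiff(names(tokens), net$places)
    if (length(unknown) > 0L)
      stop("unknown places in marking: ", paste(unknown, collapse = ", "))
    m[names(tokens)] <- as.integer(tokens)
  }
  if (any(m < 0L) || anyNA(m)) stop("token counts must be non-negative")
  class(m) <- "marking"
  m
}

check_marking <- function(net, m) {
  if (!all(net$places %in% names(m)))
    stop("marking does not cover every place of the net")
  m <- m[net$places]
  if (any(m < 0L) || anyNA(m)) stop("token counts must be non-negative")
  m
}

check_transition <- function(net, t) {
  if (length(t) != 1L || !t %in% net$transitions)
    stop("unknown transition identifier: ", t)
  t
}

#' Pre- and post-sets of a node
#'
#' `pre_arcs()` returns the arcs into a transition (its pre-places and
#' weights, read arcs included); `post_arcs()` the arcs out of it.  For a
#' place, `pre_arcs()` returns producing transitions and `post_arcs()`
#' consuming ones.
#'
#' @param net a [petri_net].
#' @param node a place or transition identifier.
#' @return subset of `net$arcs`.
#' @export
pre_arcs <- function(net, node) {
  if (node %in% net$transitions)
    net$arcs[net$arcs$dst == node, , drop = FALSE]
  else if (node %in% net$places)
    net$arcs[net$arcs$src == node & !net$arcs$read, , drop = FALSE]
  else stop("unknown node: ", node)
}

#' @rdname pre_arcs
#' @export
post_arcs <- function(net, node) {
  if (node %in% net$transitions)
    net$arcs[net$arcs$src == node, , drop = FALSE]
  else if (node %in% net$places)
    rbind(net$arcs[net$arcs$src == node, , drop = FALSE])
  else stop("unknown node: ", node)
}

#' Is a transition enabled?
#'
#' A transition is enabled when every ordinary pre-place holds at least the
#' connecting arc's weight in tokens and every read-arc place holds at least
#' one token.
#'
#' @param net a [petri_net].
#' @param m a marking covering the net's places.
#' @param t transition identifier.
#' @return logical scalar.
#' @export
is_enabled <- function(net, m, t) {
  check_transition(net, t)
  m <- check_marking(net, m)
  pre <- pre_arcs(net, t)
  all(m[pre$src] >= pre$weight)
}

#' Fire a transition
#'
#' Returns the marking after firing `t`: every ordinary pre-place loses the
#' arc weight in tokens, every post-place gains its arc weight, and read-arc
#' places are unchanged.  The input marking is not modified.
#'
#' @inheritParams is_enabled
#' @return a new `marking`.
#' @export
fire <- function(net, m, t) {
  check_transition(net, t)
  m <- check_marking(net, m)
  pre <- pre_arcs(net, t)
  short <- m[pre$src] < pre$weight
  if (any(short))
    stop(sprintf("cannot fire disabled transition %s: place %s holds %d < %d",
                 t, pre$src[short][1L], m[pre$src[short][1L]],
                 pre$weight[short][1L]))
  ord <- pre[!pre$read, , drop = FALSE]
  if (nrow(ord) > 0L)
    m[ord$src] <- m[ord$src] - ord$weight
  post <- post_arcs(net, t)
  if (nrow(post) > 0L)
    for (k in seq_len(nrow(post)))
      m[post$dst[k]] <- m[post$dst[k]] + post$weight[k]
  class(m) <- "marking"
  m
}

#' Firing policy
#'
#' Controls the scheduler of [run()].  `deterministic_sweep` repeatedly scans
#' transitions in ascending lexicographic-numeric identifier order (e.g.
#' `e2 < e10 < ea1 < t1`) and fires the first enabled one, which makes runs
#' exactly reproducible; `random_order` fires a uniformly chosen enabled
#' transition, driven by `seed`.  `max_steps` bounds the number of firings;
#' runs hitting the bound are flagged (`termination_reason = "step_budget"`),
#' not silently truncated.
#'
#' @param mode `"deterministic_sweep"` or `"random_order"`.
#' @param seed integer seed, used only by `random_order`.
#' @param max_steps positive integer firing budget.
#' @return list of class `firing_policy`.
#' @export
firing_policy <- function(mode = c("deterministic_sweep", "random_order"),
                          seed = 1L, max_steps = 10000L) {
  mode <- match.arg(mode)
  max_steps <- as.integer(max_steps)
  if (is.na(max_steps) || max_steps < 1L) stop("max_steps must be >= 1")
  structure(list(mode = mode, seed = as.integer(seed),
                 max_steps = max_steps), class = "firing_policy")
}

#' Lexicographic-numeric identifier order
#'
#' Orders identifiers by their alphabetic prefix, then numerically by the
#' digits that follow (so `t2` before `t10`, `e4` before `ea17`).
#'
#' @param ids character vector of identifiers.
#' @return integer permutation, as from [order()].
#' @export
natural_order <- function(ids) {
  prefix <- sub("^([^0-9]*).*$", "\\1", ids)
  num <- suppressWarnings(as.numeric(sub("^[^0-9]*([0-9]*).*$", "\\1", ids)))
  num[is.na(num)] <- -1
  rest <- sub("^[^0-9]*[0-9]*", "", ids)
  order(prefix, num, rest)
}

# Compile a net into the integer-indexed arrays the C++ engine consumes.
# Transitions are laid out in firing-priority (lexicographic-numeric) order.
compile_net <- function(net) {
  trans <- net$transitions[natural_order(net$transitions)]
  nT <- length(trans)
  nP <- length(net$places)
  pidx <- setNames(seq_len(nP), net$places)
  tidx <- setNames(seq_len(nT), trans)
  a <- net$arcs
  in_arcs <- a[a$dst %in% trans, , drop = FALSE]       # place -> transition
  out_arcs <- a[a$src %in% trans, , drop = FALSE]      # transition -> place
  pre_t <- tidx[in_arcs$dst]
  o <- order(pre_t)
  in_arcs <- in_arcs[o, , drop = FALSE]; pre_t <- pre_t[o]
  post_t <- tidx[out_arcs$src]
  o <- order(post_t)
  out_arcs <- out_arcs[o, , drop = FALSE]; post_t <- post_t[o]
  pre_ptr <- c(0L, cumsum(tabulate(pre_t, nT)))
  post_ptr <- c(0L, cumsum(tabulate(post_t, nT)))
  cons_p <- pidx[in_arcs$src]
  o <- order(cons_p)
  cons_ptr <- c(0L, cumsum(tabulate(cons_p[o], nP)))
  n_pre <- pre_ptr[-1L] - pre_ptr[-length(pre_ptr)]
  list(n_places = nP, n_trans = nT,
       places = net$places, transitions = trans,
       pre_ptr = pre_ptr,
       pre_place = unname(pidx[in_arcs$src] - 1L),
       pre_w = in_arcs$weight,
       pre_read = as.integer(in_arcs$read),
       post_ptr = post_ptr,
       post_place = unname(pidx[out_arcs$dst] - 1L),
       post_w = out_arcs$weight,
       cons_ptr = cons_ptr,
       cons_trans = unname(pre_t[o] - 1L),
       is_source = as.integer(n_pre == 0L))
}

#' Run a net to quiescence, target firing, or the step budget
#'
#' Executes firings under the given policy until (a) the target transition
#' fires, (b) no transition is enabled, or (c) `max_steps` firings have
#' occurred.  A source transition (empty pre-set) fires at most once per run;
#' the initial supply it models is carried by the initial marking instead.
#'
#' @param net a [petri_net].
#' @param m0 initial [marking].
#' @param policy a [firing_policy].
#' @param target transition identifier whose firing ends the run, or `NULL`.
#' @return list of class `run_result` with elements `final_marking`, `fired`
#'   (data frame of step index and transition identifier), `target_fired`,
#'   `termination_reason` (one of `"target_reached"`, `"quiescent"`,
#'   `"step_budget"`) and `steps`.
#' @export
run <- function(net, m0, policy = firing_policy(), target = NULL) {
  m0 <- check_marking(net, m0)
  if (!is.null(target)) check_transition(net, target)
  cn <- compile_net(net)
  res <- cpp_run(cn, as.integer(m0[cn$places]),
                 if (is.null(target)) -1L else
                   which(cn$transitions == target) - 1L,
                 policy$max_steps,
                 policy$mode == "deterministic_sweep",
                 as.double(policy$seed %% 2^31), TRUE)
  final <- setNames(as.integer(res$final), cn$places)[net$places]
  class(final) <- "marking"
  fired <- cn$transitions[res$fired]
  structure(
    list(final_marking = final,
         fired = data.frame(step = seq_along(fired), transition = fired,
                            stringsAsFactors = FALSE),
         target_fired = res$reason == 0L,
         termination_reason = c("target_reached", "quiescent",
                                "step_budget")[res$reason + 1L],
         steps = res$steps),
    class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %d firings, %s, target_fired=%s\n",
              x$steps, x$termination_reason, x$target_fired))
  invisible(x)
}

# Pure-R reference scheduler with identical semantics; used as an internal
# cross-check of the compiled engine.
run_r <- function(net, m0, policy = firing_policy(), target = NULL) {
  m <- check_marking(net, m0)
  if (!is.null(target)) check_transition(net, target)
  trans <- net$transitions[natural_order(net$transitions)]
  pre <- lapply(trans, function(t) pre_arcs(net, t))
  names(pre) <- trans
  sources <- vapply(pre, function(x) nrow(x) == 0L, logical(1))
  dead <- setNames(logical(length(trans)), trans)
  if (policy$mode == "random_order") set.seed(policy$seed)
  fired <- character()
  reason <- "quiescent"
  repeat {
    en <- trans[!dead & vapply(trans, function(t) {
      p <- pre[[t]]
      nrow(p) == 0L || all(m[p$src] >= p$weight)
    }, logical(1))]
    if (length(en) == 0L) break
    if (length(fired) >= policy$max_steps) { reason <- "step_budget"; break }
    t <- if (policy$mode == "deterministic_sweep") en[1L]
         else en[sample.int(length(en), 1L)]
    m <- fire(net, m, t)
    fired <- c(fired, t)
    if (sources[t]) dead[t] <- TRUE
    if (!is.null(target) && t == target) { reason <- "target_reached"; break }
  }
  class(m) <- "marking"
  structure(
    list(final_marking = m,
         fired = data.frame(step = seq_along(fired), transition = fired,
                            stringsAsFactors = FALSE),
         target_fired = !is.null(target) && target %in% fired,
         termination_reason = reason, steps = length(fired)),
    class = "run_result")
}

#' Small demonstration nets
#'
#' `demo_threshold_net()` is a three-place, one-transition net illustrating
#' weighted enabling and firing: `T1` needs 5 tokens from `p1` and 6 from
#' `p2` and produces 9 in `p3`; the bundled marking is `p1 = 10, p2 = 7,
#' p3 = 0`.  `demo_regulatory_net()` illustrates a regulatory (read) edge:
#' `T1` produces `P1`, and `T2` (consuming `P0`, producing `P2`) carries a
#' read arc from `P1`, so `T2` cannot fire until `P1` holds a token, however
#' much `P0` is present, and firing `T2` leaves `P1` unchanged.
#'
#' @return list with elements `net` (a [petri_net]) and `m0` (a [marking]).
#' @export
demo_threshold_net <- function() {
  net <- petri_net(
    places = c("p1", "p2", "p3"),
    transitions = "T1",
    arcs = data.frame(src = c("p1", "p2", "T1"),
                      dst = c("T1", "T1", "p3"),
                      weight = c(5L, 6L, 9L)))
  list(net = net, m0 = marking(net, c(p1 = 10L, p2 = 7L)))
}

#' @rdname demo_threshold_net
#' @export
demo_regulatory_net <- function() {
  net <- petri_net(
    places = c("P0", "P1", "P2"),
    transitions = c("T1", "T2"),
    arcs = data.frame(src = c("T1", "P1", "P0", "T2"),
                      dst = c("P1", "T2", "T2", "P2"),
                      weight = c(1L, 1L, 1L, 1L),
                      read = c(FALSE, TRUE, FALSE, FALSE)))
  list(net = net, m0 = marking(net, c(P0 = 1L)))
}
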