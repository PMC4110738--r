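#' Read a net-definition file
#'
#' Plain-text, newline-delimited net description with whitespace-separated
#' fields in named sections:
#'
#' ```
#' places
#' <id> <label> <initial tokens> <tags or .>
#' transitions
#' <id> <label> <tags or .>
#' arcs
#' <src> <dst> <weight> <R or .>
#' components
#' <protein name> <place id>
#' ```
#'
#' Tags are comma-joined (e.g. `psi,ste`; `fixed` marks technical-presence
#' places whose initial tokens are part of the model rather than of an
#' experiment plan).  An `R` flag marks a regulatory (read) arc.  Lines that
#' are blank or start with `#` are ignored.  The optional `components`
#' section maps protein names (as used in interaction rosters) to place
#' identifiers.
#'
#' @param path file path.
#' @return list with elements `net` (a [petri_net]), `m0` (the marking from
#'   the tokens column) and `components` (named character vector, possibly
#'   empty).
#' @seealso [write_net_definition()] for the lossless inverse.
#' @export
read_net_definition <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  section <- NA_character_
  pl <- list(); tr <- list(); ar <- list(); cmp <- list()
  for (i in which(keep)) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) == 1L &&
        fields %in% c("places", "transitions", "arcs", "components")) {
      section <- fields
      next
    }
    if (is.na(section))
      stop(sprintf("%s:%d: content before any section header", path, i))
    ok <- switch(section,
      places = length(fields) %in% 3:4,
      transitions = length(fields) %in% 2:3,
      arcs = length(fields) %in% 3:4,
      components = length(fields) == 2L)
    if (!ok)
      stop(sprintf("%s:%d: malformed %s line: '%s'", path, i, section,
                   lines[i]))
    if (section == "places") {
      tok <- suppressWarnings(as.integer(fields[3L]))
      if (is.na(tok) || tok < 0L)
        stop(sprintf("%s:%d: bad token count '%s'", path, i, fields[3L]))
      pl[[length(pl) + 1L]] <- list(id = fields[1L], label = fields[2L],
                                    tokens = tok,
                                    tags = tag_split(fields[4L]))
    } else if (section == "transitions") {
      tr[[length(tr) + 1L]] <- list(id = fields[1L], label = fields[2L],
                                    tags = tag_split(fields[3L]))
    } else if (section == "arcs") {
      w <- suppressWarnings(as.integer(fields[3L]))
      if (is.na(w) || w < 1L)
        stop(sprintf("%s:%d: bad arc weight '%s'", path, i, fields[3L]))
      flag <- if (length(fields) >= 4L) fields[4L] else "."
      if (!flag %in% c(".", "R"))
        stop(sprintf("%s:%d: unknown arc flag '%s'", path, i, flag))
      ar[[length(ar) + 1L]] <- list(src = fields[1L], dst = fields[2L],
                                    weight = w, read = flag == "R")
    } else {
      cmp[[fields[1L]]] <- fields[2L]
    }
  }
  if (length(pl) == 0L || length(tr) == 0L)
    stop(path, ": model must declare places and transitions")
  place_ids <- vapply(pl, `[[`, "", "id")
  trans_ids <- vapply(tr, `[[`, "", "id")
  arcs <- data.frame(
    src = vapply(ar, `[[`, "", "src"),
    dst = vapply(ar, `[[`, "", "dst"),
    weight = vapply(ar, `[[`, 0L, "weight"),
    read = vapply(ar, `[[`, FALSE, "read"),
    stringsAsFactors = FALSE)
  labels <- c(setNames(vapply(pl, `[[`, "", "label"), place_ids),
              setNames(vapply(tr, `[[`, "", "label"), trans_ids))
  net <- petri_net(place_ids, trans_ids, arcs, labels = labels,
                   place_tags = setNames(lapply(pl, `[[`, "tags"), place_ids),
                   transition_tags = setNames(lapply(tr, `[[`, "tags"),
                                              trans_ids))
  m0 <- marking(net, setNames(vapply(pl, `[[`, 0L, "tokens"), place_ids))
  list(net = net, m0 = m0, components = unlist(cmp) %||% character())
}

tag_split <- function(x) {
  if (is.na(x) || x == "." || x == "") character() else
    strsplit(x, ",", fixed = TRUE)[[1]]
}

tag_join <- function(x) if (length(x) == 0L) "." else paste(x, collapse = ",")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a net-definition file
#'
#' Inverse of [read_net_definition()]; a written file reads back to an
#' identical net, marking and component map.
#'
#' @param net a [petri_net].
#' @param m0 a [marking] over `net` giving the initial-tokens column.
#' @param path output file path.
#' @param components optional named character vector mapping protein names
#'   to place identifiers.
#' @param header optional comment line written at the top.
#' @return `path`, invisibly.
#' @export
write_net_definition <- function(net, m0, path, components = NULL,
                                 header = NULL) {
  m0 <- check_marking(net, m0)
  lab <- function(id) {
    l <- net$labels[id]
    ifelse(is.na(l) | l == "", id, l)
  }
  ptags <- vapply(net$places, function(p)
    tag_join(net$place_tags[[p]] %||% character()), "")
  ttags <- vapply(net$transitions, function(t)
    tag_join(net$transition_tags[[t]] %||% character()), "")
  out <- c(
    if (!is.null(header)) paste("#", header),
    "places",
    sprintf("%s\t%s\t%d\t%s", net$places, lab(net$places),
            as.integer(m0[net$places]), ptags),
    "transitions",
    sprintf("%s\t%s\t%s", net$transitions, lab(net$transitions), ttags),
    "arcs",
    sprintf("%s\t%s\t%d\t%s", net$arcs$src, net$arcs$dst, net$arcs$weight,
            ifelse(net$arcs$read, "R", ".")))
  if (length(components) > 0L)
    out <- c(out, "components",
             sprintf("%s\t%s", names(components), components))
  writeLines(out, path)
  invisible(path)
}
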