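#' Stoichiometric metabolic networks
#'
#' A `metabolic_network` stores a lumped stoichiometric model: a full
#' stoichiometric matrix over all metabolites, a flag per metabolite marking it
#' as extracellular (unbalanced) or intracellular (balanced at steady state),
#' and a reversibility flag per reaction. Balanced rows form `S_int`, the
#' matrix whose null-space cone is spanned by the elementary flux modes;
#' external rows form `S_ext`, used to project modes onto macroscopic
#' exchange stoichiometries.
#'
#' @param metabolites data.frame with columns `id`, `name`, `external`.
#' @param reactions data.frame with columns `id`, `reversible`, and optionally
#'   `lumped` (marks lumped pathway reactions, e.g. amino-acid catabolism).
#' @param S full stoichiometric matrix, metabolites x reactions, with
#'   dimnames matching the ids above.
#' @return An object of class `metabolic_network`.
#' @export
metabolic_network <- function(metabolites, reactions, S) {
  stopifnot(is.data.frame(metabolites), is.data.frame(reactions), is.matrix(S))
  if (anyDuplicated(metabolites$id)) stop("duplicate metabolite id: ",
    paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  if (anyDuplicated(reactions$id)) stop("duplicate reaction id: ",
    paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))
  if (is.null(reactions$lumped)) reactions$lumped <- FALSE
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  S <- clean_zeros(S)
  dimnames(S) <- list(metabolites$id, reactions$id)
  for (j in seq_len(ncol(S))) {
    if (ncol(S) > 0 && all(S[, j] == 0))
      stop("reaction ", reactions$id[j], " has no nonzero coefficient")
  }
  structure(list(metabolites = metabolites, reactions = reactions, S = S),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network> %d reactions, %d internal + %d external metabolites\n",
              n_reactions(x), sum(!x$metabolites$external), sum(x$metabolites$external)))
  invisible(x)
}

#' Network accessors
#'
#' `S_int()` returns the balanced (intracellular) rows of the stoichiometric
#' matrix, `S_ext()` the external rows, `reversibilities()` the per-reaction
#' reversibility flags, and `n_reactions()` the reaction count.
#'
#' @param net a `metabolic_network`.
#' @return matrix / logical vector / integer as appropriate.
#' @export
S_int <- function(net) net$S[!net$metabolites$external, , drop = FALSE]

#' @rdname S_int
#' @export
S_ext <- function(net) net$S[net$metabolites$external, , drop = FALSE]

#' @rdname S_int
#' @export
reversibilities <- function(net) stats::setNames(as.logical(net$reactions$reversible),
                                                 net$reactions$id)

#' @rdname S_int
#' @export
n_reactions <- function(net) nrow(net$reactions)

#' Build a network from reaction equation strings
#'
#' Equations use the dialect `"a A + b B -> c C"`; metabolites suffixed
#' `"_ext"` are extracellular (unbalanced). A `"<->"` arrow marks the reaction
#' reversible (equivalently set the `reversible` flag). Coefficients with
#' magnitude below 1e-12 are treated as zero.
#'
#' @param ids character reaction ids.
#' @param equations character equation strings.
#' @param reversible logical vector (recycled); `"<->"` in an equation wins.
#' @param lumped logical vector (recycled).
#' @return a `metabolic_network`.
#' @export
network_from_equations <- function(ids, equations, reversible = FALSE,
                                   lumped = FALSE) {
  stopifnot(length(ids) == length(equations))
  reversible <- rep_len(as.logical(reversible), length(ids))
  lumped <- rep_len(as.logical(lumped), length(ids))
  parsed <- lapply(equations, parse_equation)
  rev2 <- reversible | vapply(parsed, `[[`, logical(1), "reversible")
  mets <- unique(unlist(lapply(parsed, function(p) names(p$stoich))))
  S <- matrix(0, length(mets), length(ids), dimnames = list(mets, ids))
  for (j in seq_along(parsed)) S[names(parsed[[j]]$stoich), j] <- parsed[[j]]$stoich
  metabolites <- data.frame(id = mets, name = mets,
                            external = grepl("_ext$", mets),
                            stringsAsFactors = FALSE)
  metabolic_network(metabolites,
                    data.frame(id = ids, reversible = rev2, lumped = lumped,
                               stringsAsFactors = FALSE), S)
}

parse_equation <- function(eq) {
  rev <- grepl("<->|<=>", eq)
  sides <- strsplit(eq, "<->|<=>|->|=>", perl = TRUE)[[1]]
  if (length(sides) != 2) stop("cannot parse equation: ", eq)
  stoich <- numeric(0)
  add_side <- function(side, sign, acc) {
    side <- trimws(side)
    if (side == "" || side == "0") return(acc)
    for (term in trimws(strsplit(side, "+", fixed = TRUE)[[1]])) {
      if (term == "") next
      m <- regmatches(term, regexec("^([0-9.eE+-]+\\s+)?(\\S+)$", term))[[1]]
      coef <- if (is.na(m[2]) || m[2] == "") 1 else as.numeric(trimws(m[2]))
      met <- m[3]
      acc[met] <- (if (met %in% names(acc)) acc[[met]] else 0) + sign * coef
    }
    acc
  }
  stoich <- add_side(sides[1], -1, stoich)
  stoich <- add_side(sides[2], +1, stoich)
  stoich <- stoich[abs(stoich) >= 1e-12]
  list(stoich = stoich, reversible = rev)
}

format_equation <- function(stoich) {
  fmt_side <- function(v) {
    if (length(v) == 0) return("0")
    paste(ifelse(abs(abs(v) - 1) < 1e-12, names(v),
                 paste(format(abs(v), trim = TRUE, digits = 12), names(v))),
          collapse = " + ")
  }
  lhs <- stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  paste(fmt_side(lhs), "->", fmt_side(rhs))
}

#' Read a metabolic network from disk
#'
#' Two formats are supported. `"tsv"` is a reaction table with one reaction
#' per row and columns `id`, `reversible` (0/1), `equation` (see
#' [network_from_equations()]) and optionally `lumped`; external metabolites
#' carry the `_ext` suffix. `"sbml"` is a minimal SBML level-2 reader mapping
#' species `boundaryCondition="true"` to the external flag.
#'
#' @param path file path.
#' @param format `"tsv"` or `"sbml"`.
#' @return a validated `metabolic_network`; the load is a lossless round-trip
#'   with [write_network()].
#' @export
load_network <- function(path, format = c("tsv", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path)
  if (format == "tsv") {
    lines <- readLines(path)
    decl <- grep("^#\\s*metabolite\\s", lines, value = TRUE)
    tab <- utils::read.delim(textConnection(lines), comment.char = "#",
                             stringsAsFactors = FALSE)
    need <- c("id", "reversible", "equation")
    if (!all(need %in% names(tab)))
      stop("network TSV must have columns: ", paste(need, collapse = ", "))
    net <- network_from_equations(tab$id, tab$equation,
                                  reversible = as.logical(tab$reversible),
                                  lumped = if ("lumped" %in% names(tab))
                                    as.logical(tab$lumped) else FALSE)
    if (length(decl)) {
      declared <- vapply(strsplit(trimws(sub("^#\\s*metabolite\\s+", "", decl)),
                                  "\\s+"), `[`, character(1), 1)
      missing <- setdiff(net$metabolites$id, declared)
      if (length(missing))
        stop("reaction references undeclared metabolite: ",
             paste(missing, collapse = ", "))
    }
    net
  } else {
    load_sbml(path)
  }
}

load_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  met_id <- xml2::xml_attr(sp, "id")
  external <- tolower(xml2::xml_attr(sp, "boundaryCondition")) %in% "true"
  met_name <- xml2::xml_attr(sp, "name")
  met_name[is.na(met_name)] <- met_id[is.na(met_name)]
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxn_id <- xml2::xml_attr(rx, "id")
  reversible <- !(tolower(xml2::xml_attr(rx, "reversible")) %in% "false")
  S <- matrix(0, length(met_id), length(rxn_id), dimnames = list(met_id, rxn_id))
  for (j in seq_along(rx)) {
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(rx[[j]], paste0("./", side, "/speciesReference"))
      for (ref in refs) {
        sid <- xml2::xml_attr(ref, "species")
        if (!sid %in% met_id) stop("reaction ", rxn_id[j],
                                   " references undeclared metabolite ", sid)
        st <- xml2::xml_attr(ref, "stoichiometry")
        S[sid, j] <- S[sid, j] + sgn * (if (is.na(st)) 1 else as.numeric(st))
      }
    }
  }
  metabolic_network(
    data.frame(id = met_id, name = met_name, external = external,
               stringsAsFactors = FALSE),
    data.frame(id = rxn_id, reversible = reversible, lumped = FALSE,
               stringsAsFactors = FALSE), S)
}

#' Write a metabolic network to disk
#'
#' Inverse of [load_network()]: `load_network(write_network(net, p), fmt)`
#' reproduces `net` exactly (ids, coefficients, flags).
#'
#' @param net a `metabolic_network`.
#' @inheritParams load_network
#' @export
write_network <- function(net, path, format = c("tsv", "sbml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    eqs <- vapply(seq_len(n_reactions(net)), function(j) {
      v <- net$S[, j]
      format_equation(v[v != 0])
    }, character(1))
    tab <- data.frame(id = net$reactions$id,
                      reversible = as.integer(net$reactions$reversible),
                      equation = eqs,
                      lumped = as.integer(net$reactions$lumped))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write_sbml(net, path)
  }
  invisible(NULL)
}

write_sbml <- function(net, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">')
  w('<model id="model"><listOfSpecies>')
  for (i in seq_len(nrow(net$metabolites)))
    w(sprintf('<species id="%s" name="%s" boundaryCondition="%s"/>',
              esc(net$metabolites$id[i]), esc(net$metabolites$name[i]),
              tolower(net$metabolites$external[i])))
  w('</listOfSpecies><listOfReactions>')
  for (j in seq_len(n_reactions(net))) {
    v <- net$S[, j]
    w(sprintf('<reaction id="%s" reversible="%s">',
              esc(net$reactions$id[j]), tolower(net$reactions$reversible[j])))
    for (side in c(-1, 1)) {
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      sel <- which(sign(v) == side)
      if (length(sel)) {
        w(sprintf('<%s>', tag))
        for (i in sel)
          w(sprintf('<speciesReference species="%s" stoichiometry="%s"/>',
                    esc(rownames(net$S)[i]), format(abs(v[i]), digits = 15)))
        w(sprintf('</%s>', tag))
      }
    }
    w('</reaction>')
  }
  w('</listOfReactions></model></sbml>')
  invisible(NULL)
}

#' Reduce a network to a kept set of reactions
#'
#' Removing a reaction is equivalent to adding a null-flux constraint for it;
#' metabolites left with no incident reaction are dropped so the balanced
#' matrix stays full-rank.
#'
#' @param net a `metabolic_network`.
#' @param keep character vector of reaction ids to retain.
#' @return the reduced `metabolic_network`.
#' @export
reduce_network <- function(net, keep) {
  unknown <- setdiff(keep, net$reactions$id)
  if (length(unknown)) stop("unknown reaction id in keep: ",
                            paste(unknown, collapse = ", "))
  keep_j <- net$reactions$id %in% keep
  if (!any(keep_j)) warning("reduce_network: empty reaction set")
  S <- net$S[, keep_j, drop = FALSE]
  incident <- rowSums(abs(S)) > 0
  metabolic_network(net$metabolites[incident, , drop = FALSE],
                    net$reactions[keep_j, , drop = FALSE],
                    S[incident, , drop = FALSE])
}

#' Degrees-of-freedom accounting for metabolic flux analysis
#'
#' The minimum number of measured fluxes required for a determined MFA system
#' is `nr - rank(S_int)`; with more measurements the system is redundant and
#' the surplus is the redundancy available for consistency testing.
#'
#' @param net a `metabolic_network`.
#' @param measured character vector of measured (exchange) flux ids.
#' @return list with `min_required`, `redundancy`, and `underdetermined`.
#' @export
dof_summary <- function(net, measured = character(0)) {
  stopifnot(all(measured %in% net$reactions$id))
  min_required <- n_reactions(net) - mat_rank(S_int(net))
  redundancy <- length(measured) - min_required
  list(min_required = as.integer(min_required),
       redundancy = as.integer(redundancy),
       underdetermined = redundancy < 0)
}

#' Exchange reactions of a network
#'
#' Reactions with at least one external metabolite coefficient; these are the
#' measurable uptake/secretion fluxes.
#'
#' @param net a `metabolic_network`.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(net) {
  net$reactions$id[colSums(abs(S_ext(net))) > 0]
}

networks_equal <- function(a, b, tol = 1e-9) {
  identical(a$metabolites$id, b$metabolites$id) &&
    identical(a$reactions$id, b$reactions$id) &&
    identical(as.logical(a$metabolites$external), as.logical(b$metabolites$external)) &&
    identical(as.logical(a$reactions$reversible), as.logical(b$reactions$reversible)) &&
    max(abs(a$S - b$S)) <= tol
}
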