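#' Elementary flux mode sets
#'
#' An `elementary_mode_set` holds the matrix `E` (reactions x modes) of
#' elementary flux modes of a network: the minimal, non-decomposable
#' steady-state flux distributions from which every steady-state flux vector
#' is a non-negative combination (negative weights are admissible only for
#' fully reversible modes, stored once with `fully_reversible = TRUE`).
#'
#' Modes are kept in a canonical form: each column is scaled so its smallest
#' nonzero absolute coefficient is 1, fully reversible modes are oriented so
#' their first nonzero entry is positive, and columns are ordered
#' lexicographically by support (ties broken by the first nonzero
#' coefficient). This makes enumeration output deterministic across runs.
#'
#' @param E numeric matrix, reactions x modes, rownames = reaction ids.
#' @param fully_reversible logical per mode: the negated mode is also valid.
#' @param reversible logical per reaction (used for validation).
#' @return object of class `elementary_mode_set` with elements `E`,
#'   `fully_reversible`, `n_modes`, and optional `flags`.
#' @export
elementary_mode_set <- function(E, fully_reversible = NULL, reversible = NULL) {
  stopifnot(is.matrix(E))
  if (is.null(colnames(E)) && ncol(E) > 0) colnames(E) <- paste0("m", seq_len(ncol(E)))
  if (is.null(fully_reversible)) {
    if (is.null(reversible)) stop("need fully_reversible or reversible flags")
    fully_reversible <- apply(E != 0, 2, function(s) all(reversible[s]))
  }
  structure(list(E = E, fully_reversible = as.logical(fully_reversible),
                 n_modes = ncol(E), flags = NULL),
            class = "elementary_mode_set")
}

#' @export
print.elementary_mode_set <- function(x, ...) {
  cat(sprintf("<elementary_mode_set> %d modes over %d reactions (%d fully reversible)\n",
              x$n_modes, nrow(x$E), sum(x$fully_reversible)))
  invisible(x)
}

canonical_scale_mode <- function(v, fully_rev = FALSE, tol = 1e-9) {
  v <- clean_zeros(v, tol * max(abs(v)))
  nz <- which(v != 0)
  if (!length(nz)) return(v)
  v <- v / min(abs(v[nz]))
  if (fully_rev && v[nz[1]] < 0) v <- -v
  v
}

order_modes <- function(E) {
  if (ncol(E) <= 1) return(seq_len(ncol(E)))
  keys <- lapply(seq_len(ncol(E)), function(j) {
    s <- which(E[, j] != 0)
    list(supp = s, first = E[s[1], j])
  })
  do.call(order, list(vapply(keys, function(k)
    paste(sprintf("%05d", k$supp), collapse = ","), character(1)),
    vapply(keys, `[[`, numeric(1), "first")))
}

canonicalize_modes <- function(E, reversible, tol = 1e-9) {
  if (ncol(E) == 0) return(list(E = E, fully_reversible = logical(0)))
  fr <- apply(E != 0, 2, function(s) all(reversible[s]))
  for (j in seq_len(ncol(E))) E[, j] <- canonical_scale_mode(E[, j], fr[j], tol)
  # drop duplicates (equal up to the canonical scaling, incl. +/- pairs of
  # fully reversible modes which canonical orientation has already merged)
  keep <- !duplicated(lapply(seq_len(ncol(E)), function(j) round(E[, j], 9)))
  E <- E[, keep, drop = FALSE]
  fr <- fr[keep]
  o <- order_modes(E)
  E <- E[, o, drop = FALSE]
  colnames(E) <- paste0("m", seq_len(ncol(E)))
  list(E = E, fully_reversible = fr[o])
}

#' Enumerate elementary flux modes
#'
#' Double-description enumeration on the pointed cone obtained by splitting
#' reversible reactions into forward/backward pairs: starting from the
#' non-negative orthant, the balance constraint of each intracellular
#' metabolite is intersected in turn, combining positive/negative ray pairs
#' and keeping only rays with minimal support. Split directions are
#' recombined afterwards, spurious forward/backward two-cycles removed, and
#' the +/- copies of fully reversible modes merged.
#'
#' @param net a `metabolic_network`.
#' @param max_modes abort with an error if the working ray set exceeds this
#'   cap (guards against combinatorial explosion).
#' @return an `elementary_mode_set` in canonical order.
#' @export
enumerate_ems <- function(net, max_modes = 1e6) {
  nr <- n_reactions(net)
  if (nr == 0) stop("empty network")
  rev <- reversibilities(net)
  Si <- S_int(net)
  # split reversible columns
  split_cols <- cbind(Si, -Si[, rev, drop = FALSE])
  orig_of <- c(seq_len(nr), which(rev))
  sign_of <- c(rep(1, nr), rep(-1, sum(rev)))
  ns <- ncol(split_cols)
  rays <- diag(ns)  # rows = split reactions, cols = rays
  supp <- lapply(seq_len(ns), function(i) i)
  for (i in seq_len(nrow(split_cols))) {
    d <- as.numeric(split_cols[i, ] %*% rays)
    d[abs(d) < 1e-12 * max(1, max(abs(d)))] <- 0
    zero <- which(d == 0); pos <- which(d > 0); neg <- which(d < 0)
    new_rays <- rays[, zero, drop = FALSE]
    new_supp <- supp[zero]
    if (length(pos) && length(neg)) {
      for (p in pos) for (q in neg) {
        u <- union(supp[[p]], supp[[q]])
        # adjacency (support-minimality) test against all other current rays
        adjacent <- TRUE
        for (k in seq_along(supp)) {
          if (k == p || k == q) next
          if (all(supp[[k]] %in% u)) { adjacent <- FALSE; break }
        }
        if (!adjacent) next
        v <- d[p] * rays[, q] - d[q] * rays[, p]
        v <- v / max(abs(v))
        v[abs(v) < 1e-12] <- 0
        new_rays <- cbind(new_rays, v)
        new_supp <- c(new_supp, list(which(v != 0)))
      }
    }
    if (ncol(new_rays) > max_modes)
      stop("elementary-mode cap exceeded (", max_modes,
           "); raise max_modes if this network is really that large")
    rays <- new_rays
    supp <- new_supp
  }
  # recombine split reversible directions
  E <- matrix(0, nr, ncol(rays), dimnames = list(net$reactions$id, NULL))
  for (k in seq_len(ncol(rays))) {
    v <- numeric(nr)
    for (s in which(rays[, k] != 0)) v[orig_of[s]] <- v[orig_of[s]] + sign_of[s] * rays[s, k]
    E[, k] <- clean_zeros(v, 1e-12 * max(abs(v), 1))
  }
  nonzero <- colSums(E != 0) > 0
  E <- E[, nonzero, drop = FALSE]
  cm <- canonicalize_modes(E, rev)
  ems <- elementary_mode_set(cm$E, cm$fully_reversible)
  validate_ems(ems, net)
  ems
}

validate_ems <- function(ems, net, tol = 1e-9) {
  if (ems$n_modes == 0) return(invisible(TRUE))
  Si <- S_int(net)
  rev <- reversibilities(net)
  if (nrow(Si) > 0) {
    resid <- abs(Si %*% ems$E)
    scale <- apply(abs(ems$E), 2, max)
    bad <- which(apply(resid, 2, max) > tol * pmax(scale, 1))
    if (length(bad)) stop("mode ", paste(colnames(ems$E)[bad], collapse = ", "),
                          " violates the steady-state balance")
  }
  for (j in seq_len(ems$n_modes)) {
    v <- ems$E[, j]
    if (!ems$fully_reversible[j] && any(v[!rev] < -tol))
      stop("mode ", colnames(ems$E)[j],
           " has negative flux through an irreversible reaction")
  }
  invisible(TRUE)
}

#' Brute-force elementary-mode oracle
#'
#' Exhaustively tests every reaction-support subset of a small network
#' (`nr <= 14`): a support is an elementary mode iff the null space of the
#' balanced matrix restricted to it is one-dimensional, fully nonzero on the
#' support, sign-feasible with respect to irreversibilities, and minimal (no
#' kept support strictly contained in it). Independent of [enumerate_ems()]
#' and used to cross-check it.
#'
#' @inheritParams enumerate_ems
#' @return an `elementary_mode_set` in the same canonical form.
#' @export
oracle_enumerate <- function(net) {
  nr <- n_reactions(net)
  if (nr > 14) stop("oracle limited to networks with at most 14 reactions")
  rev <- reversibilities(net)
  Si <- S_int(net)
  cand <- list()
  supports <- list()
  for (mask in seq_len(2^nr - 1)) {
    s <- which(bitwAnd(mask, bitwShiftL(1, seq_len(nr) - 1)) != 0)
    N <- null_basis(Si[, s, drop = FALSE])
    if (ncol(N) != 1) next
    v <- as.numeric(N)
    if (any(abs(v) < 1e-9)) next  # support not exact -> covered by a subset
    full <- numeric(nr); full[s] <- v
    irr <- s[!rev[s]]
    if (length(irr)) {
      sg <- sign(full[irr])
      if (any(sg > 0) && any(sg < 0)) next
      if (all(sg < 0)) full <- -full
    }
    cand[[length(cand) + 1]] <- full
    supports[[length(supports) + 1]] <- s
  }
  keep <- rep(TRUE, length(cand))
  for (i in seq_along(cand)) for (j in seq_along(cand)) {
    if (i != j && keep[i] &&
        length(supports[[j]]) < length(supports[[i]]) &&
        all(supports[[j]] %in% supports[[i]])) keep[i] <- FALSE
  }
  E <- if (any(keep)) do.call(cbind, cand[keep]) else matrix(0, nr, 0)
  rownames(E) <- net$reactions$id
  cm <- canonicalize_modes(E, rev)
  elementary_mode_set(cm$E, cm$fully_reversible)
}

#' Compress a network before mode enumeration
#'
#' Applies the standard pre-processing for elementary-mode computation:
#' iterative removal of reactions coupled to dead-end intracellular
#' metabolites (metabolites that cannot be both produced and consumed), and
#' merging of strictly-coupled unbranched reaction pairs (an intracellular
#' metabolite incident to exactly two reactions with opposite-sign
#' coefficients forces a fixed flux ratio). Returns the compressed network
#' together with an expansion matrix mapping compressed modes back to the
#' original reaction space.
#'
#' @param net a `metabolic_network`.
#' @return list with `net` (compressed), `expand` (nr_original x
#'   nr_compressed matrix), and `dropped` (ids of removed reactions).
#' @export
compress_network <- function(net) {
  orig_ids <- net$reactions$id
  cur <- net
  M <- diag(n_reactions(net))
  rownames(M) <- orig_ids
  repeat {
    changed <- FALSE
    Si <- S_int(cur)
    rev <- reversibilities(cur)
    if (nrow(Si) == 0 || n_reactions(cur) == 0) break
    # dead-end removal
    for (i in seq_len(nrow(Si))) {
      row <- Si[i, ]
      producers <- which(row > 0 | (rev & row < 0))
      consumers <- which(row < 0 | (rev & row > 0))
      incident <- which(row != 0)
      if (length(incident) && (length(producers) == 0 || length(consumers) == 0)) {
        keep <- setdiff(seq_len(n_reactions(cur)), incident)
        M <- M[, keep, drop = FALSE]
        cur <- reduce_network(cur, cur$reactions$id[keep])
        changed <- TRUE
        break
      }
    }
    if (changed) next
    # strictly coupled pair merging
    Si <- S_int(cur); rev <- reversibilities(cur)
    merged <- FALSE
    for (i in seq_len(nrow(Si))) {
      inc <- which(Si[i, ] != 0)
      if (length(inc) != 2) next
      a <- Si[i, inc[1]]; b <- Si[i, inc[2]]
      k <- -a / b
      if (k <= 0) {
        if (!rev[inc[1]] && !rev[inc[2]]) {
          keep <- setdiff(seq_len(n_reactions(cur)), inc)
          M <- M[, keep, drop = FALSE]
          cur <- reduce_network(cur, cur$reactions$id[keep])
          merged <- TRUE
          break
        }
        next  # sign-coupled through a reversible pair: leave uncompressed
      }
      newcol <- cur$S[, inc[1]] + k * cur$S[, inc[2]]
      newM <- M[, inc[1]] + k * M[, inc[2]]
      keep <- setdiff(seq_len(n_reactions(cur)), inc)
      ids <- cur$reactions$id
      newid <- paste(ids[inc[1]], ids[inc[2]], sep = "+")
      S2 <- cbind(cur$S[, keep, drop = FALSE], clean_zeros(newcol))
      rx2 <- rbind(cur$reactions[keep, , drop = FALSE],
                   data.frame(id = newid,
                              reversible = rev[inc[1]] && rev[inc[2]],
                              lumped = TRUE))
      colnames(S2) <- rx2$id
      incident <- rowSums(abs(S2)) > 0
      cur <- metabolic_network(cur$metabolites[incident, , drop = FALSE],
                               rx2, S2[incident, , drop = FALSE])
      M <- cbind(M[, keep, drop = FALSE], newM)
      colnames(M) <- rx2$id
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  colnames(M) <- cur$reactions$id
  list(net = cur, expand = M, dropped = setdiff(orig_ids, rownames(M)[rowSums(abs(M)) > 0]))
}

#' Re-expand modes of a compressed network to the original reaction space
#'
#' @param ems `elementary_mode_set` computed on `compress_network(net)$net`.
#' @param compression the list returned by [compress_network()].
#' @param net the original network (for canonical re-ordering/validation).
#' @return an `elementary_mode_set` over the original reactions.
#' @export
expand_modes <- function(ems, compression, net) {
  E <- compression$expand %*% ems$E
  rownames(E) <- net$reactions$id[match(rownames(compression$expand),
                                        net$reactions$id)]
  E <- E[net$reactions$id, , drop = FALSE]
  cm <- canonicalize_modes(E, reversibilities(net))
  out <- elementary_mode_set(cm$E, cm$fully_reversible)
  validate_ems(out, net)
  out
}

#' Project a mode onto extracellular compounds
#'
#' The macroscopic reaction of a mode is its image under the external
#' stoichiometry, `S_ext %*% flux`, with zero coefficients dropped. When a
#' reference substrate is given the rendering is normalized so that compound
#' has coefficient 1 (in absolute value).
#'
#' @param flux numeric flux vector over the reactions of `net` (a column of
#'   an `elementary_mode_set`).
#' @param net the `metabolic_network`.
#' @param reference optional external compound id used to normalize.
#' @return named numeric vector of signed external coefficients (empty, with
#'   a warning, for a purely internal cycle).
#' @export
project_external <- function(flux, net, reference = NULL) {
  macro <- as.numeric(S_ext(net) %*% flux)
  names(macro) <- rownames(S_ext(net))
  macro <- macro[abs(macro) > 1e-9 * max(abs(macro), 1)]
  if (!length(macro)) {
    warning("mode has an all-zero external projection (internal cycle)")
    return(macro)
  }
  if (!is.null(reference) && reference %in% names(macro))
    macro <- macro / abs(macro[[reference]])
  macro
}

#' Render a macroscopic reaction as text
#'
#' @param macro named coefficients as returned by [project_external()].
#' @return a string in the style `"a A + b B -> c C"` (consumed on the left).
#' @export
format_macro <- function(macro) {
  format_equation(macro)
}

#' Classify modes by biomass and product synthesis
#'
#' A mode makes biomass (or product) when it carries nonzero flux through the
#' named synthesis reaction.
#'
#' @param ems an `elementary_mode_set`.
#' @param biomass_id,product_id reaction ids (either may be `NULL`).
#' @return the mode set with a `flags` data.frame (`makes_biomass`,
#'   `makes_product`).
#' @export
classify_modes <- function(ems, biomass_id = NULL, product_id = NULL) {
  chk <- function(id) {
    if (!is.null(id) && !id %in% rownames(ems$E))
      stop("unknown reaction id: ", id)
  }
  chk(biomass_id); chk(product_id)
  nz <- function(id) if (is.null(id)) rep(FALSE, ems$n_modes) else
    abs(ems$E[id, ]) > 1e-9
  ems$flags <- data.frame(mode = colnames(ems$E) %||% character(0),
                          makes_biomass = nz(biomass_id),
                          makes_product = nz(product_id))
  ems
}

#' Read / write an elementary-mode matrix as TSV
#'
#' The interchange format is a TSV with reaction ids as rows and mode names
#' as columns (the layout produced by METATOOL/FluxAnalyzer-style exports);
#' a `# fully_reversible:` comment line preserves the reversibility flags so
#' the round-trip is lossless. On import against a network the steady-state
#' and sign invariants are re-verified.
#'
#' @param path file path.
#' @param net optional `metabolic_network` to validate against.
#' @return an `elementary_mode_set`.
#' @export
read_em_matrix <- function(path, net = NULL) {
  lines <- readLines(path)
  frline <- grep("^#\\s*fully_reversible:", lines, value = TRUE)
  tab <- utils::read.delim(textConnection(lines), comment.char = "#",
                           row.names = 1, check.names = FALSE)
  E <- as.matrix(tab)
  fr <- rep(FALSE, ncol(E))
  if (length(frline)) {
    ids <- strsplit(trimws(sub("^#\\s*fully_reversible:", "", frline[1])), "\\s+")[[1]]
    fr <- colnames(E) %in% ids
  }
  if (!is.null(net)) {
    if (!identical(rownames(E), net$reactions$id))
      stop("EM matrix rows do not match the network's reactions")
    resid <- abs(S_int(net) %*% E)
    bad <- which(apply(resid, 2, max) > 1e-6 * pmax(apply(abs(E), 2, max), 1))
    if (length(bad))
      stop("mode ", paste(colnames(E)[bad], collapse = ", "),
           " violates the steady-state balance of the supplied network")
    return(elementary_mode_set(E, fully_reversible = fr))
  }
  elementary_mode_set(E, fully_reversible = fr)
}

#' @rdname read_em_matrix
#' @param ems an `elementary_mode_set`.
#' @export
write_em_matrix <- function(ems, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (any(ems$fully_reversible))
    writeLines(paste("# fully_reversible:",
                     paste(colnames(ems$E)[ems$fully_reversible], collapse = " ")),
               con)
  utils::write.table(data.frame(reaction = rownames(ems$E), ems$E,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

ems_equal <- function(a, b, tol = 1e-8) {
  if (a$n_modes != b$n_modes) return(FALSE)
  if (a$n_modes == 0) return(TRUE)
  all(abs(a$E - b$E) <= tol * pmax(abs(a$E), 1)) &&
    identical(a$fully_reversible, b$fully_reversible)
}
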