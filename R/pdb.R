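# Wire-model serialization in a Protein Data Bank format dialect.
#
# Dialect (documented in inst/extdata/wire-model-pdb-dialect.md): one HETATM
# record per node with micrometer coordinates written directly into the
# x/y/z fields (the format's nominal Angstrom unit is repurposed); the trace
# id lives in the residue-sequence field, wrapping into successive chain
# identifiers beyond 9999; the node diameter (um) is stored in the
# temperature-factor column; node names occupy the atom-name field;
# connections are CONECT records.  Writing is canonical, so a
# write -> read -> write round trip is byte-identical.

pdb_chain_ids <- c(LETTERS, letters, as.character(0:9))

#' Write a wire model in the PDB dialect
#'
#' @param model a [wire_model()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_pdb_model <- function(model, path) {
  stopifnot(inherits(model, "wire_model"))
  n <- nrow(model$nodes)
  if (n > 99999L)
    stopf("model has %d nodes; the serial field holds at most 99999", n,
          class = "axotomo_overflow_error")
  if (n > 0 && max(abs(as.matrix(model$nodes[, c("x", "y", "z")]))) >= 1e5)
    stopf("coordinates exceed the fixed-width field range (|um| < 1e5)",
          class = "axotomo_overflow_error")
  con <- file(path, "wb")  # binary mode: LF line endings on every platform
  on.exit(close(con))
  wl <- function(s) writeLines(s, con, sep = "\n")
  wl("REMARK   3 SKELETONIZED AXONAL TRACT WIRE MODEL")
  wl("REMARK   3 COORDINATES IN MICROMETERS (X/Y/Z FIELDS REPURPOSED)")
  wl("REMARK   3 TRACE ID = RESSEQ + 9999 * CHAIN INDEX; B-FACTOR = NODE DIAMETER (UM)")
  wl("REMARK   3 AXES: -X/+X DORSOVENTRAL, -Y/+Y LEFT-TO-RIGHT, -Z/+Z ANTEROPOSTERIOR")
  if (n > 0) {
    trace <- model$nodes$trace
    res <- ((trace - 1L) %% 9999L) + 1L
    chain_i <- ((trace - 1L) %/% 9999L) + 1L
    if (max(chain_i) > length(pdb_chain_ids))
      stopf("too many traces for the chain identifier alphabet",
            class = "axotomo_overflow_error")
    for (i in seq_len(n)) {
      wl(sprintf("HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                 i, substr(model$nodes$name[i], 1, 4), "TRC",
                 pdb_chain_ids[chain_i[i]], res[i],
                 model$nodes$x[i], model$nodes$y[i], model$nodes$z[i],
                 1, model$nodes$diameter[i]))
    }
    cn <- model$connections
    if (nrow(cn) > 0) {
      for (from in sort(unique(cn[, 1]))) {
        partners <- sort(cn[cn[, 1] == from, 2])
        while (length(partners)) {
          take <- head(partners, 4)
          partners <- tail(partners, -length(take))
          wl(paste0("CONECT", sprintf("%5d", from),
                    paste(sprintf("%5d", take), collapse = "")))
        }
      }
    }
  }
  wl("END")
  invisible(path)
}

#' Read a wire model from the PDB dialect
#'
#' @param path file written by [write_pdb_model()] (or hand-built in the
#'   same dialect).
#' @return a [wire_model()].
#' @export
read_pdb_model <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  atom_lines <- which(rec %in% c("HETATM", "ATOM  "))
  serial <- integer(0); trace <- integer(0); name <- character(0)
  xyz <- matrix(numeric(0), 0, 3); dia <- numeric(0)
  num <- function(s, ln, what) {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v))
      stopf("line %d: malformed %s field '%s'", ln, what, trimws(s),
            class = "axotomo_parse_error")
    v
  }
  for (ln in atom_lines) {
    l <- lines[ln]
    if (nchar(l) < 66)
      stopf("line %d: coordinate record too short (%d chars)", ln, nchar(l),
            class = "axotomo_parse_error")
    serial <- c(serial, as.integer(num(substr(l, 7, 11), ln, "serial")))
    name <- c(name, trimws(substr(l, 13, 16)))
    chain <- substr(l, 22, 22)
    ci <- match(chain, pdb_chain_ids)
    if (is.na(ci))
      stopf("line %d: unknown chain identifier '%s'", ln, chain,
            class = "axotomo_parse_error")
    res <- as.integer(num(substr(l, 23, 26), ln, "residue-sequence"))
    trace <- c(trace, (ci - 1L) * 9999L + res)
    xyz <- rbind(xyz, c(num(substr(l, 31, 38), ln, "x"),
                        num(substr(l, 39, 46), ln, "y"),
                        num(substr(l, 47, 54), ln, "z")))
    dia <- c(dia, num(substr(l, 61, 66), ln, "temperature-factor"))
  }
  if (length(serial) == 0) return(wire_model())
  if (any(duplicated(serial)))
    stopf("duplicate atom serial numbers", class = "axotomo_parse_error")
  ord <- order(serial)
  index_of_serial <- function(s, ln) {
    i <- match(s, serial[ord])
    if (is.na(i))
      stopf("line %d: CONECT references unknown serial %d", ln, s,
            class = "axotomo_parse_error")
    i
  }
  conns <- list()
  for (ln in which(rec == "CONECT")) {
    l <- lines[ln]
    from <- as.integer(num(substr(l, 7, 11), ln, "CONECT serial"))
    fi <- index_of_serial(from, ln)
    p <- 12
    while (p + 4 <= nchar(l)) {
      fld <- trimws(substr(l, p, p + 4))
      if (nzchar(fld)) {
        ti <- index_of_serial(as.integer(num(fld, ln, "CONECT partner")), ln)
        conns[[length(conns) + 1L]] <- c(fi, ti)
      }
      p <- p + 5
    }
  }
  # renumber traces serially in order of first appearance
  tr <- trace[ord]
  ids <- unique(tr)
  nodes <- tibble::tibble(trace = match(tr, ids), name = name[ord],
                          x = xyz[ord, 1], y = xyz[ord, 2], z = xyz[ord, 3],
                          diameter = dia[ord])
  wire_model(nodes, if (length(conns)) do.call(rbind, conns) else NULL)
}

#' Export a wire model to SWC (extension)
#'
#' SWC is the common interchange format of neuron-morphology tools; this
#' export is an interoperability extension, not part of the PDB dialect.
#' Each trace becomes a tree rooted at its first node (parent -1); extra
#' connections that would create cycles are dropped with a warning.
#'
#' @param model a [wire_model()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_swc_model <- function(model, path) {
  stopifnot(inherits(model, "wire_model"))
  n <- nrow(model$nodes)
  parent <- rep(-1L, n)
  if (n > 0 && nrow(model$connections) > 0) {
    adj <- vector("list", n)
    for (i in seq_len(nrow(model$connections))) {
      a <- model$connections[i, 1]; b <- model$connections[i, 2]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
    seen <- logical(n)
    dropped <- 0L
    for (tr in unique(model$nodes$trace)) {
      root <- which(model$nodes$trace == tr)[1]
      queue <- root; seen[root] <- TRUE
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        for (nb in adj[[cur]]) {
          if (seen[nb]) { if (parent[cur] != nb) dropped <- dropped + 1L; next }
          seen[nb] <- TRUE; parent[nb] <- cur; queue <- c(queue, nb)
        }
      }
    }
    if (dropped > 0)
      warning(sprintf("dropped %d cycle-forming connections in SWC export",
                      dropped))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("# SWC export of an axonal tract wire model",
               "# id type x y z radius parent (coordinates in um)"),
             con, sep = "\n")
  if (n > 0)
    writeLines(sprintf("%d 0 %.3f %.3f %.3f %.3f %d", seq_len(n),
                       model$nodes$x, model$nodes$y, model$nodes$z,
                       model$nodes$diameter / 2, parent),
               con, sep = "\n")
  invisible(path)
}
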