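#' Read and write Gmsh MSH meshes
#'
#' ASCII Gmsh MSH files in format 2.2 or 4.1 with physical groups. Physical
#' surface groups become facet tags, physical volume groups become subdomain
#' tags. Writing always emits format 4.1 with full-precision (`%.17g`)
#' coordinates, so a write/read round trip reproduces the mesh bit-exactly.
#'
#' @param path file path.
#' @param mesh a [stim_mesh()].
#' @return `read_mesh` returns a [stim_mesh()]; `write_mesh` returns the path,
#'   invisibly.
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  fmt_i <- match("$MeshFormat", lines)
  if (is.na(fmt_i)) stop("not a Gmsh MSH file (no $MeshFormat section): ", path)
  ver <- as.numeric(strsplit(trimws(lines[fmt_i + 1]), "\\s+")[[1]][1])
  if (ver >= 4) read_msh41(lines) else read_msh22(lines)
}

msh_section <- function(lines, name) {
  i0 <- match(paste0("$", name), lines)
  if (is.na(i0)) return(NULL)
  i1 <- match(paste0("$End", name), lines)
  lines[(i0 + 1):(i1 - 1)]
}

parse_physical_names <- function(lines) {
  sec <- msh_section(lines, "PhysicalNames")
  if (is.null(sec)) {
    stop("MSH file has no physical groups; required tags are named physical ",
         "surfaces (facet tags) and physical volumes (subdomain tags)")
  }
  n <- as.integer(sec[1])
  out <- data.frame(dim = integer(n), tag = integer(n), name = character(n))
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(sec[i + 1]), "\\s+")[[1]]
    out$dim[i] <- as.integer(parts[1])
    out$tag[i] <- as.integer(parts[2])
    out$name[i] <- gsub('"', "", paste(parts[-(1:2)], collapse = " "))
  }
  out
}

scan_nums <- function(txt) scan(text = txt, quiet = TRUE)

read_msh22 <- function(lines) {
  phys <- parse_physical_names(lines)
  nsec <- msh_section(lines, "Nodes")
  nn <- as.integer(nsec[1])
  ntab <- matrix(scan_nums(nsec[-1]), ncol = 4, byrow = TRUE)
  id_map <- integer(max(ntab[, 1]))
  id_map[ntab[, 1]] <- seq_len(nn)
  nodes <- ntab[, 2:4, drop = FALSE]

  esec <- msh_section(lines, "Elements")
  ne <- as.integer(esec[1])
  facets <- list(); subtets <- list()
  tets <- NULL
  for (ln in esec[-1]) {
    v <- scan_nums(ln)
    type <- v[2]; ntags <- v[3]
    ptag <- if (ntags >= 1) v[4] else 0L
    conn <- v[(4 + ntags):length(v)]
    if (type == 2) {
      nm <- phys$name[phys$dim == 2 & phys$tag == ptag]
      nm <- if (length(nm)) nm else paste0("surface_", ptag)
      facets[[nm]] <- rbind(facets[[nm]], id_map[conn])
    } else if (type == 4) {
      nm <- phys$name[phys$dim == 3 & phys$tag == ptag]
      nm <- if (length(nm)) nm else paste0("volume_", ptag)
      tets <- rbind(tets, id_map[conn])
      subtets[[nm]] <- c(subtets[[nm]], nrow(tets))
    } else {
      stop("unsupported MSH element type ", type,
           " (only triangles [2] and tetrahedra [4] are supported)")
    }
  }
  finish_read(nodes, tets, facets, subtets)
}

read_msh41 <- function(lines) {
  phys <- parse_physical_names(lines)
  # entity -> physical tag map
  esec <- msh_section(lines, "Entities")
  counts <- as.integer(scan_nums(esec[1]))
  ent_phys <- list(`2` = list(), `3` = list())
  i <- 2 + counts[1] + counts[2]  # skip points and curves
  for (s in seq_len(counts[3])) {
    v <- scan_nums(esec[i]); i <- i + 1
    nph <- v[8]
    if (nph >= 1) ent_phys[["2"]][[as.character(as.integer(v[1]))]] <- as.integer(v[9])
  }
  for (s in seq_len(counts[4])) {
    v <- scan_nums(esec[i]); i <- i + 1
    nph <- v[8]
    if (nph >= 1) ent_phys[["3"]][[as.character(as.integer(v[1]))]] <- as.integer(v[9])
  }

  nsec <- msh_section(lines, "Nodes")
  hdr <- scan_nums(nsec[1])
  nblocks <- hdr[1]; nn <- hdr[2]
  ids <- integer(nn); xyz <- matrix(0, nn, 3)
  i <- 2; filled <- 0
  for (b in seq_len(nblocks)) {
    bh <- scan_nums(nsec[i]); i <- i + 1
    nb <- bh[4]
    if (nb == 0) next
    tag_i <- as.integer(nsec[i:(i + nb - 1)]); i <- i + nb
    coords <- matrix(scan_nums(nsec[i:(i + nb - 1)]), ncol = 3, byrow = TRUE)
    i <- i + nb
    ids[filled + seq_len(nb)] <- tag_i
    xyz[filled + seq_len(nb), ] <- coords
    filled <- filled + nb
  }
  id_map <- integer(max(ids))
  id_map[ids] <- seq_len(nn)

  elsec <- msh_section(lines, "Elements")
  hdr <- scan_nums(elsec[1])
  nblocks <- hdr[1]
  facets <- list(); subtets <- list(); tets <- NULL
  i <- 2
  for (b in seq_len(nblocks)) {
    bh <- scan_nums(elsec[i]); i <- i + 1
    dim <- bh[1]; etag <- as.integer(bh[2]); type <- bh[3]; nb <- bh[4]
    if (nb == 0) next
    block <- matrix(scan_nums(elsec[i:(i + nb - 1)]), nrow = nb, byrow = TRUE)
    i <- i + nb
    if (type == 2 && dim == 2) {
      ptag <- ent_phys[["2"]][[as.character(etag)]]
      nm <- phys$name[phys$dim == 2 & phys$tag == ptag]
      nm <- if (length(nm)) nm else paste0("surface_", etag)
      facets[[nm]] <- rbind(facets[[nm]],
                            matrix(id_map[block[, 2:4]], ncol = 3))
    } else if (type == 4 && dim == 3) {
      ptag <- ent_phys[["3"]][[as.character(etag)]]
      nm <- phys$name[phys$dim == 3 & phys$tag == ptag]
      nm <- if (length(nm)) nm else paste0("volume_", etag)
      new_tets <- matrix(id_map[block[, 2:5]], ncol = 4)
      base <- if (is.null(tets)) 0L else nrow(tets)
      tets <- rbind(tets, new_tets)
      subtets[[nm]] <- c(subtets[[nm]], base + seq_len(nb))
    } else {
      stop("unsupported MSH element type ", type, " (dim ", dim, ")",
           "; only triangles [2] and tetrahedra [4] are supported")
    }
  }
  finish_read(xyz, tets, facets, subtets)
}

finish_read <- function(nodes, tets, facets, subtets) {
  if (is.null(tets)) stop("MSH file contains no tetrahedra")
  facets <- lapply(facets, function(f) {
    storage.mode(f) <- "integer"
    f
  })
  storage.mode(tets) <- "integer"
  stim_mesh(nodes, tets, facets = facets, subdomains = subtets)
}

#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path) {
  ftags <- names(mesh$facets)
  stags <- names(mesh$subdomains)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("$MeshFormat", "4.1 0 8", "$EndMeshFormat")

  w("$PhysicalNames", as.character(length(ftags) + length(stags)))
  for (i in seq_along(ftags)) w(sprintf('2 %d "%s"', i, ftags[i]))
  for (i in seq_along(stags)) w(sprintf('3 %d "%s"', length(ftags) + i, stags[i]))
  w("$EndPhysicalNames")

  bb <- apply(mesh$nodes, 2, range)
  bbs <- paste(sprintf("%.17g", c(bb[1, ], bb[2, ])), collapse = " ")
  w("$Entities", paste(0, 0, length(ftags), length(stags)))
  for (i in seq_along(ftags)) w(paste(i, bbs, 1, i, 0))
  for (i in seq_along(stags)) w(paste(i, bbs, 1, length(ftags) + i, 0))
  w("$EndEntities")

  nn <- nrow(mesh$nodes)
  w("$Nodes", paste(1, nn, 1, nn), paste(3, 1, 0, nn))
  writeLines(as.character(seq_len(nn)), con)
  writeLines(sprintf("%.17g %.17g %.17g",
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  w("$EndNodes")

  nelem <- sum(vapply(mesh$facets, nrow, 1L)) + nrow(mesh$tets)
  w("$Elements", paste(length(ftags) + length(stags), nelem, 1, nelem))
  eid <- 0L
  for (i in seq_along(ftags)) {
    f <- mesh$facets[[i]]
    w(paste(2, i, 2, nrow(f)))
    writeLines(sprintf("%d %d %d %d", eid + seq_len(nrow(f)),
                       f[, 1], f[, 2], f[, 3]), con)
    eid <- eid + nrow(f)
  }
  for (i in seq_along(stags)) {
    sel <- mesh$subdomains[[i]]
    tt <- mesh$tets[sel, , drop = FALSE]
    w(paste(3, i, 4, nrow(tt)))
    writeLines(sprintf("%d %d %d %d %d", eid + seq_len(nrow(tt)),
                       tt[, 1], tt[, 2], tt[, 3], tt[, 4]), con)
    eid <- eid + nrow(tt)
  }
  w("$EndElements")
  invisible(path)
}
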