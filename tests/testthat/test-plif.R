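# plif module: pharmacophore typing, interaction detection, Tanimoto,
# summaries

bs_from_table <- function(tab, id = "cx", site = "cofactor") {
  tab$chain <- "A"
  tab$icode <- ""
  tab$uid <- paste0("A:", tab$resnum, ":_")
  tab$is_backbone <- !tab$is_ligand & tab$name %in% c("N", "CA", "C", "O", "OXT")
  pocketmap:::new_bs_complex(id, id, site, tab)
}

test_that("protein templates: backbone carbonyl acceptor, Lys NZ donor+cation", {
  tab <- data.frame(
    name = c("N", "CA", "C", "O", "NZ", "C1"),
    element = c("N", "C", "C", "O", "N", "C"),
    x = c(0, 1.5, 2.2, 2.2, 30, 60), y = c(0, 0, 1.2, 2.4, 0, 0), z = 0,
    resnum = c(1, 1, 1, 1, 2, 90),
    resname = c("ALA", "ALA", "ALA", "ALA", "LYS", "LIG"),
    is_ligand = c(rep(FALSE, 5), TRUE), stringsAsFactors = FALSE
  )
  cx <- bs_from_table(tab)
  ann <- annotate_pharmacophores(cx)
  expect_true(ann$acceptor[cx$atoms$name == "O"])
  expect_true(ann$donor[cx$atoms$name == "N" & cx$atoms$resname == "ALA"])
  expect_true(ann$donor[cx$atoms$name == "NZ"])
  expect_true(ann$cation[cx$atoms$name == "NZ"])
})

test_that("ligand carboxylate oxygens are typed anionic acceptors", {
  tab <- data.frame(
    name = c("CA", "C1", "O1", "O2", "C2"),
    element = c("C", "C", "O", "O", "C"),
    x = c(50, 0, 1.25, -1.25, 0), y = c(0, 0, 0, 0, 1.5), z = 0,
    resnum = c(1, 90, 90, 90, 90),
    resname = c("ALA", rep("LIG", 4)),
    is_ligand = c(FALSE, rep(TRUE, 4)), stringsAsFactors = FALSE
  )
  ann <- annotate_pharmacophores(bs_from_table(tab))
  o <- which(tab$name %in% c("O1", "O2"))
  expect_true(all(ann$anion[o]))
  expect_true(all(ann$acceptor[o]))
  expect_false(any(ann$donor[o]))  # carboxylate O are not donors
})

hb_fixture <- function(side_chain_contact = FALSE) {
  # ligand N donor with antecedent C, 2.9 A from a backbone O, angle 150
  ante <- c(2.9 + 1.4 * cos(pi * 30 / 180), 1.4 * sin(pi * 30 / 180), 0)
  tab <- data.frame(
    name = c("O", "OG", "N1", "C1"),
    element = c("O", "O", "N", "C"),
    x = c(0, if (side_chain_contact) 0.5 else 40, 2.9, ante[1]),
    y = c(0, 1.0, 0, ante[2]), z = 0,
    resnum = c(1, 1, 90, 90),
    resname = c("SER", "SER", "LIG", "LIG"),
    is_ligand = c(FALSE, FALSE, TRUE, TRUE), stringsAsFactors = FALSE
  )
  bs_from_table(tab)
}

test_that("hydrogen bond detected once per residue regardless of atom multiplicity", {
  cx <- hb_fixture(side_chain_contact = FALSE)
  fp <- detect_interactions(cx, annotate_pharmacophores(cx), manual_map(cx, 10))
  expect_equal(sum(fp$bits$type == "HBD" & fp$bits$column == 10), 1)
  # add a second qualifying contact via the side-chain OG: still one bit
  cx2 <- hb_fixture(side_chain_contact = TRUE)
  fp2 <- detect_interactions(cx2, annotate_pharmacophores(cx2), manual_map(cx2, 10))
  expect_equal(sum(fp2$bits$type == "HBD" & fp2$bits$column == 10), 1)
})

test_that("angle proxy rejects a bent donor geometry", {
  # antecedent placed so that angle(acceptor-donor-antecedent) is ~60 deg
  tab <- data.frame(
    name = c("O", "N1", "C1"),
    element = c("O", "N", "C"),
    x = c(0, 2.9, 2.9 - 1.4 * cos(pi * 60 / 180)),
    y = c(0, 0, 1.4 * sin(pi * 60 / 180)), z = 0,
    resnum = c(1, 90, 90), resname = c("GLY", "LIG", "LIG"),
    is_ligand = c(FALSE, TRUE, TRUE), stringsAsFactors = FALSE
  )
  cx <- bs_from_table(tab)
  fp <- detect_interactions(cx, annotate_pharmacophores(cx), manual_map(cx, 3))
  expect_false(any(fp$bits$type == "HBD"))
  expect_true(any(fp$bits$type == "SURFACE"))  # contact remains a surface bit
})

test_that("distant ligands give empty fingerprints", {
  tab <- data.frame(
    name = c("O", "N1"), element = c("O", "N"),
    x = c(0, 20), y = 0, z = 0, resnum = c(1, 90),
    resname = c("GLY", "LIG"), is_ligand = c(FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  cx <- bs_from_table(tab)
  fp <- detect_interactions(cx, annotate_pharmacophores(cx), manual_map(cx, 1))
  expect_equal(nrow(fp$bits), 0)
})

test_that("detect_interactions is rigid-motion invariant", {
  tc <- make_toy_complex(toy3_spec(seed = 11, distances = c(2.9, 3.4),
                                   roles = c("donor", "none")))
  cx <- load_complex(tc$path, "A", "LIG", site = "cofactor")
  map <- manual_map(cx, c(5, 6, 7))
  fp <- detect_interactions(cx, annotate_pharmacophores(cx), map)
  cxr <- rigid_transform_complex(cx, seed = 3)
  fpr <- detect_interactions(cxr, annotate_pharmacophores(cxr), map)
  expect_equal(fp$bits, fpr$bits)
})

test_that("Tanimoto: identity, disjointness, set arithmetic, edge cases", {
  f1 <- manual_fp("a", data.frame(column = c(1, 2, 3),
                                  type = c("HBD", "HBA", "SURFACE")))
  f2 <- manual_fp("b", data.frame(column = c(2, 3, 4),
                                  type = c("HBA", "SURFACE", "HBD")))
  expect_equal(fingerprint_tanimoto(f1, f1), 1)
  expect_equal(fingerprint_tanimoto(f1, f2), 2 / 4)
  f3 <- manual_fp("c", data.frame(column = c(9, 10), type = c("IONIC", "ARENE")))
  expect_equal(fingerprint_tanimoto(f1, f3), 0)
  empty <- manual_fp("e", data.frame(column = integer(0), type = character(0)))
  expect_warning(t0 <- fingerprint_tanimoto(empty, empty), "empty")
  expect_equal(t0, 0)
  sub <- manual_fp("s", data.frame(column = 1, type = "HBD"), site = "substrate")
  expect_error(fingerprint_tanimoto(f1, sub), "site mismatch")
  # property: symmetric, in [0,1], 1 iff equal bit sets
  set.seed(1)
  for (k in 1:20) {
    b1 <- unique(data.frame(column = sample(5, 3, TRUE),
                            type = sample(c("HBD", "HBA", "SURFACE"), 3, TRUE)))
    b2 <- unique(data.frame(column = sample(5, 3, TRUE),
                            type = sample(c("HBD", "HBA", "SURFACE"), 3, TRUE)))
    g1 <- manual_fp("g1", b1); g2 <- manual_fp("g2", b2)
    t12 <- fingerprint_tanimoto(g1, g2)
    expect_identical(t12, fingerprint_tanimoto(g2, g1))
    expect_gte(t12, 0); expect_lte(t12, 1)
    same <- setequal(paste(b1$column, b1$type), paste(b2$column, b2$type))
    expect_identical(t12 == 1, same)
  }
})

test_that("interaction summaries: per-bit percentages and type shares", {
  fps <- list(
    manual_fp("c1", data.frame(column = c(10, 11), type = c("HBD", "SURFACE"))),
    manual_fp("c2", data.frame(column = 10, type = "HBD")),
    manual_fp("c3", data.frame(column = 12, type = "HBA")),
    manual_fp("c4", data.frame(column = 13, type = "ARENE"))
  )
  s <- summarize_interactions(fps)
  hit <- s$per_bit[s$per_bit$column == 10 & s$per_bit$type == "HBD", ]
  expect_equal(hit$percent, 50)
  expect_equal(sum(s$per_type$percent), 100)
  expect_setequal(s$interacting_columns, c(10, 11, 12, 13))
  # single complex, 3 HBD + 1 SURFACE -> shares 75/25
  one <- list(manual_fp("c1", data.frame(column = 1:4,
                                         type = c("HBD", "HBD", "HBD", "SURFACE"))))
  s1 <- summarize_interactions(one)
  expect_equal(s1$per_type$percent[s1$per_type$type == "HBD"], 75)
  expect_equal(s1$per_type$percent[s1$per_type$type == "SURFACE"], 25)
  # per-target grouping counts a bit once per target
  grouping <- c(c1 = "T1", c2 = "T1", c3 = "T2", c4 = "T2")
  sg <- summarize_interactions(fps, grouping)
  hitg <- sg$per_bit[sg$per_bit$column == 10 & sg$per_bit$type == "HBD", ]
  expect_equal(hitg$percent, 50)  # 1 of 2 targets
})
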