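# ptcsig

Rule-based annotation of **putrescine transcarbamylases (PTC)** versus
**ornithine transcarbamylases (OTC)** from protein sequence, plus the
quantitative machinery that supports that annotation: enzyme-kinetics
fitting with catalytic efficiency, a transcarbamylation equilibrium
solver, and a small structural geometry kernel (superposition RMSD,
solvent accessibility, interface burial, metal coordination).

## The problem

PTC and OTC are close homologs that both transfer a carbamyl group from
carbamylphosphate (CP) to an amine — putrescine for PTC (in the
agmatine fermentation pathway, where PTC makes the CP that drives ATP
synthesis), L-ornithine for OTC. Because the two enzymes are so similar,
PTC genes are routinely misannotated as OTCs in genome databases.
`ptcsig` implements a structure-derived sequence signature that separates
them using five rules, stated in *Enterococcus faecalis* PTC numbering:

1. **Anchors** — the invariant CP-binding `STRT` (position 52) and
   amine-binding `HCLP` (position 268) tetrapeptides, shared by both
   families, located as a pair at family spacing (190–240 residues).
   Without them a sequence is not recognized as a transcarbamylase.
2. **Lysine upstream** — OTCs carry a lysine two residues upstream of
   STRT (it ion-pairs the α-carboxylate of ornithine); PTCs replace it,
   typically with glutamine (Q50).
3. **230 loop vs SMG loop** — ~40 residues upstream of HCLP, OTCs have
   the characteristic `xSMG` loop; PTCs instead have the
   specificity-determining 230 loop `(Y/W)(G/W)(V/L/I)X`
   (`²²⁷DVWYGLY²³³` in *E. faecalis* PTC).
4. **C-terminal extension** — PTCs are ~20 residues longer past HCLP.
5. **Helix-13 signature** — the PTC-exclusive C-terminal helix
   (residues 320–337) carries the weak but constant signature
   `(L/f/v/i/m)XX(F/Y/L/M/v)(L/i/m)` in a region of high predicted
   α-helix propensity (scored here with Chou–Fasman parameters,
   window mean > 1.05 over 15 residues).

Degenerate motifs use the family-signature notation: capitals are
predominant residues, lower case lower-frequency residues, `X` any
residue. All five rules PTC-like ⇒ **PTC**; the three OTC-discriminant
rules OTC-like ⇒ **OTC**; otherwise the verdict is an unclassified
transcarbamylase, with per-rule evidence always reported.

The kinetics module fits saturation data to the hyperbola
v = V·S/(Km+S) and reports catalytic efficiency V/Km
(U mg⁻¹ mM⁻¹, 1 U = 1 µmol min⁻¹); it also fits logistic inhibition
curves (e.g. for the bisubstrate analog PAPU) and solves the
A + B ⇌ C + D equilibrium x² = Keq(a₀−x)(b₀−x) in closed form.
The structure module implements Kabsch superposition, Shrake–Rupley
SASA (1.4 Å probe), interface burial and metal-site geometry calls
(e.g. the octahedral Ni site on the PTC trimer axis, coordinated by
three His N and three water O atoms).

## Worked example

```r
library(ptcsig)

# a seeded synthetic PTC-like sequence with all five traits implanted
p <- generate_ptc_like(1)
classify(p)
#> <classification_report> ptc_like_seed1: PTC (score 5/5)
#>   anchors          ptc_like     STRT@52,HCLP@268,spacing=216 [family anchors (shared with OTC)]
#>   lysine_upstream  ptc_like     Q50
#>   loop230          ptc_like     YGLY@230
#>   cterm_extension  ptc_like     tail=69
#>   helix13          ptc_like     LAAFL@330,prop=1.22

# the engineered 230-loop swap (YGLY -> VSMG) flips exactly that rule
classify(ablate(p, "loop230"))$verdict
#> [1] "TRANSCARBAMYLASE_UNCLASSIFIED"

# wild-type putrescine kinetics: Vmax 813 U/mg, Km 1.41 mM
s <- c(0.5, 1, 2, 5, 10, 20, 40)                 # mM
fit_hyperbola(s, 813 * s / (1.41 + s), substrate = "putrescine")
#> <hyperbolic_fit> putrescine
#>   Vmax = 813 +/- 9.2e-15 U/mg
#>   Km   = 1.41 +/- 6.9e-17 mM
#>   Vmax/Km = 576.6 U mg^-1 mM^-1                  # 577 at 3 s.f.

# ornithine carbamylation equilibrium: Keq = 81, 10 mM + 10 mM
equilibrium_conversion(81, 10, 10)
#> [1] 0.9                                          # 90% conversion
```

The classification report means: both active-site anchors were found at
the family spacing (216 residues), position 50 holds glutamine rather
than the OTC lysine, the PTC 230-loop core `YGLY` sits 38 residues
upstream of HCLP with no SMG loop, the tail past HCLP is 69 residues
(PTC-length), and the helix-13 signature `LAAFL` lies in a
helix-favoring context (mean propensity 1.22).

A command-line wrapper is installed at `inst/scripts/ptcsig-cli`:

```sh
ptcsig-cli classify --in seqs.fasta --out report.tsv
ptcsig-cli generate --class ptc --n 50 --seed 1 --out fixtures.fasta
ptcsig-cli fit-kinetics --model mm --in saturation.tsv
ptcsig-cli struct metal --pdb site.pdb --element NI
```

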