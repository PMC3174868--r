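# nmrcase

Computer-assisted structure elucidation (CASE) for small molecules:
exhaustive generation of molecular constitutions from 2D NMR correlation
data, plus a **statistical filter** that removes candidates containing
atom environments never observed in a reference corpus of known molecules.

## Who this is for

Natural-product and NMR spectroscopists (and method developers) who have a
molecular formula, HSQC-derived proton counts, and COSY / ¹³C-HMBC /
¹⁵N-HMBC / 1,1-ADEQUATE correlation lists, and want the complete set of
constitutions consistent with that evidence — then a principled way to
shrink it. The package is equally usable as a library (tibble-friendly
functions, `tidy()`/`glance()`/`autoplot()` methods) or via its CLI.

## The method

Each correlation constrains the bond-path length between two heavy atoms:

| experiment   | meaning                      | allowed path lengths |
|--------------|------------------------------|----------------------|
| COSY         | vicinal ³J(H,H)              | {1}                  |
| ¹³C-HMBC     | ²J/³J H→C (ambiguous)        | {1, 2}               |
| ¹⁵N-HMBC     | ²J/³J H→N (ambiguous)        | {1, 2}               |
| 1,1-ADEQUATE | one-bond C–C                 | {1}                  |

`enumerate_constitutions()` performs a complete, canonically deduplicated
search over all connected bond-order assignments satisfying the formula,
per-atom valences (C=4, N=3, O=2, S=2, halogens=1), fixed or open
hybridizations, and every constraint (a constraint is satisfied when *some*
simple path of an allowed length joins the atoms). A naive
generate-then-filter oracle (`brute_force_enumerate()`) independently
verifies the result sets in the test suite.

The filter re-casts "no force-field parameters exist for this fragment" as
a dictionary test on **one-sphere (radius-1) environments**: the key of an
atom is its element, charge, H count and sorted (neighbor element, bond
order) multiset — e.g. `CH2(C:1,O:1)` for the methylene of ethanol. A
candidate survives iff every key occurs in a reference dictionary built
from a corpus (`build_reference()`); a candidate whose chemistry is fully
precedented can therefore never be removed. Survivors are not ranked.

## Worked example

Ethanol from its NMR evidence: formula C2H6O, two sp³ carbons with 3 and 2
attached protons (HSQC), one COSY and one HMBC cross peak.

```r
library(nmrcase)

atoms <- atom_specs(id = c("C1", "C2"), element = "C",
                    n_h = c(3, 2), hybridization = "sp3")
constraints <- compile_constraints(
  correlation_set(cosy = list(c("C1", "C2")),
                  hmbc = list(c("C1", "C2"))),
  atoms
)
cands <- enumerate_constitutions("C2H6O", atoms, constraints)
tidy(cands)
#> # A tibble: 1 × 4
#>   smiles key                     n_heavy n_rings
#>   <chr>  <chr>                     <int>   <int>
#> 1 CCO    CH2,CH3,OH1|1-2:1,1-3:1       3       0
```

One constitution: the correlation data pin ethanol down exactly. Now filter
a two-candidate set {ethanol, dimethyl ether} against a reference that only
knows ethanol:

```r
report <- filter_candidates(c(cands$constitutions, parse_smiles("COC")),
                            build_reference(cands$constitutions))
report
#> <filter_report> 1 kept / 1 removed (reduction  50.0%)
summarize_missing(report)
#> # A tibble: 2 × 2
#>   env_key       n_candidates
#>   <chr>                <int>
#> 1 CH3(O:1)                 1
#> 2 OH0(C:1,C:1)             1
```

Dimethyl ether is removed because two of its environments — a methyl on
oxygen and an ether oxygen — never occur in the (one-molecule) corpus; the
missing-key table is how you diagnose *which* substructure the filter
rejected.

The same workflow from a shell (the script lives at `inst/cli/nmrcase` in
the source tree, or `system.file("cli", "nmrcase", package = "nmrcase")`
once installed):

```sh
nmrcase simulate mol.smi --experiments cosy,hmbc -o in.json --seed 1
nmrcase buildref corpus.smi -o ref.tsv
nmrcase pipeline in.json --ref ref.tsv -o kept.smi --report report.json
```

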