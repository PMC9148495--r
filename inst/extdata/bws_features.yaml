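# Controlled vocabulary for the two-tier Beckwith-Wiedemann clinical score.
# Cardinal categories score 2 points, suggestive categories 1 point; each
# category counts at most once per proband. `patterns` are case-insensitive
# regular expressions matched against the free-text feature; a feature also
# matching an `exclude` pattern does not count for that category.
cardinal:
  macroglossia:
    patterns: ["macroglossia"]
  exomphalos:
    patterns: ["exomphalos", "omphalocele"]
  lateralized_overgrowth:
    # hemihyperplasia / body asymmetry / limb dysmetria; facial asymmetry is
    # a craniofacial sign, not lateralized overgrowth
    patterns: ["lateralized overgrowth", "hemihyper", "dysmetria", "asymmetry"]
    exclude: ["face asymmetry", "facial asymmetry"]
  hyperinsulinism:
    patterns: ["hyperinsulin"]
  multifocal_wilms_tumour:
    patterns: ["wilms", "nephroblastomatosis"]
  adrenal_cortex_cytomegaly:
    patterns: ["adrenal.*cytomegaly"]
  placental_mesenchymal_dysplasia:
    patterns: ["placental mesenchymal dysplasia"]
  pancreatic_adenomatosis:
    patterns: ["pancreatic adenomatosis"]
suggestive:
  macrosomia:
    patterns: ["macrosomia", "birth ?weight"]
  naevus_simplex:
    patterns: ["n(a)?evus flammeus", "n(a)?evus simplex"]
  polyhydramnios_placentomegaly:
    patterns: ["polyhydramnios", "placentomegaly"]
  ear_creases_or_pits:
    patterns: ["ear.*(crease|pit)", "(crease|pit).*ear"]
  neonatal_hypoglycaemia:
    # transient neonatal hypoglycaemia; unqualified hypoglycaemia in an
    # older child is not the neonatal sign
    patterns:
      - "(neonatal|perinatal|transient).*hypoglyc"
      - "hypoglyc.*(neonatal|perinatal|transient)"
  embryonal_tumour:
    patterns: ["hepatoblastoma", "neuroblastoma", "rhabdomyosarcoma", "embryonal tum"]
  organomegaly:
    patterns: ["nephromegaly", "hepatomegaly", "splenomegaly", "organomegaly"]
  abdominal_wall_defect:
    patterns: ["umbilical hernia", "diastasis recti"]
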