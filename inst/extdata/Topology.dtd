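<!--
  Document type definition for the .top topology file format.

  A Topology holds source metadata, nuclei, critical points and the
  gradient vector field of a scalar function of R^3.

  Conventions:
    * All coordinates and scalar values are atomic units; the mandatory
      Topology "unit" attribute must be "bohr" (readers reject others
      rather than silently converting).
    * All index attributes are 0-based. CriticalPoint and Nucleus
      elements carry their own index; every *Ref element and the bcp /
      rcp / ccp / nacp / cp_start / cp_end attributes refer to those
      indices. The reserved critical-point index -1 denotes the point at
      infinity (truncated gradient paths); such paths also carry
      terminus="infinity".
    * Numeric fields are serialized with 12 significant digits.
-->
<!ELEMENT Topology (SourceInformation, Nucleus*, CriticalPoint*, GradientVectorField)>
<!ATTLIST Topology unit CDATA #REQUIRED>

<!ELEMENT SourceInformation EMPTY>
<!ATTLIST SourceInformation
  qm_method            CDATA ""
  basis_set            CDATA ""
  wavefunction_program CDATA ""
  qct_program          CDATA "">

<!ELEMENT PositionVector EMPTY>
<!ATTLIST PositionVector x CDATA #REQUIRED y CDATA #REQUIRED z CDATA #REQUIRED>

<!ELEMENT Nucleus (PositionVector)>
<!ATTLIST Nucleus index CDATA #REQUIRED element CDATA #REQUIRED>

<!ELEMENT Point (PositionVector, Scalar*)>
<!ELEMENT Scalar EMPTY>
<!ATTLIST Scalar name CDATA #REQUIRED value CDATA #REQUIRED>

<!ELEMENT CriticalPoint (Point, Eigenvalues?, Eigenvectors?)>
<!ATTLIST CriticalPoint
  index     CDATA #REQUIRED
  rank      CDATA #REQUIRED
  signature CDATA #REQUIRED
  label     CDATA #REQUIRED>
<!ELEMENT Eigenvalues EMPTY>
<!ATTLIST Eigenvalues l1 CDATA #REQUIRED l2 CDATA #REQUIRED l3 CDATA #REQUIRED>
<!ELEMENT Eigenvectors (PositionVector, PositionVector, PositionVector)>

<!ELEMENT GradientVectorField
  (MolecularGraph?, Ring*, Cage*, RingSurface*, AtomicBasin*,
   InteratomicSurface*, AtomicSurface*, Envelope*)>

<!ELEMENT MolecularGraph (AtomicInteractionLine*)>
<!ELEMENT AtomicInteractionLine (GradientPath, GradientPath)>
<!ATTLIST AtomicInteractionLine bcp CDATA #REQUIRED>

<!ELEMENT GradientPath (Point, Point+)>
<!ATTLIST GradientPath
  cp_start CDATA #REQUIRED
  cp_end   CDATA #REQUIRED
  terminus CDATA #IMPLIED>

<!ELEMENT Ring (AtomicInteractionLineRef, AtomicInteractionLineRef,
                AtomicInteractionLineRef+)>
<!ATTLIST Ring rcp CDATA #REQUIRED>
<!ELEMENT AtomicInteractionLineRef EMPTY>
<!ATTLIST AtomicInteractionLineRef index CDATA #REQUIRED>

<!ELEMENT Cage (RingRef, RingRef+)>
<!ATTLIST Cage ccp CDATA #REQUIRED>
<!ELEMENT RingRef EMPTY>
<!ATTLIST RingRef index CDATA #REQUIRED>

<!ELEMENT RingSurface (GradientPath*)>
<!ATTLIST RingSurface rcp CDATA #REQUIRED>

<!ELEMENT AtomicBasin (GradientPath*)>
<!ATTLIST AtomicBasin nacp CDATA #REQUIRED>

<!ELEMENT InteratomicSurface (GradientPath*, Triangulation?)>
<!ATTLIST InteratomicSurface index CDATA #REQUIRED bcp CDATA #REQUIRED>

<!ELEMENT AtomicSurface (InteratomicSurfaceRef*)>
<!ATTLIST AtomicSurface nacp CDATA #REQUIRED>
<!ELEMENT InteratomicSurfaceRef EMPTY>
<!ATTLIST InteratomicSurfaceRef index CDATA #REQUIRED>

<!ELEMENT Envelope (Triangulation)>
<!ATTLIST Envelope nacp CDATA #REQUIRED isovalue CDATA #REQUIRED>

<!ELEMENT Triangulation (PositionVector*, Edge*, Face*)>
<!ELEMENT Edge EMPTY>
<!ATTLIST Edge a CDATA #REQUIRED b CDATA #REQUIRED>
<!ELEMENT Face EMPTY>
<!ATTLIST Face a CDATA #REQUIRED b CDATA #REQUIRED c CDATA #REQUIRED>
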