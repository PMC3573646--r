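<?xml version="1.0" encoding="UTF-8"?>
<!-- Schema for the CML subset written by fragtree::export_cml().
     One molecule element per fragment ion (display-dialect formula, the
     elemental formula path as ref, parent link by id reference) and one
     spectrum element per MS level holding the peaks that reference the
     molecules. Full CML conformance is not claimed. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema"
           targetNamespace="http://www.xml-cml.org/schema"
           xmlns:cml="http://www.xml-cml.org/schema"
           elementFormDefault="qualified">

  <xs:element name="cml">
    <xs:complexType>
      <xs:sequence>
        <xs:element ref="cml:moleculeList"/>
        <xs:element ref="cml:spectrumList"/>
      </xs:sequence>
      <xs:attribute name="convention" type="xs:string" use="required"/>
      <xs:attribute name="title" type="xs:string"/>
    </xs:complexType>
  </xs:element>

  <xs:element name="moleculeList">
    <xs:complexType>
      <xs:sequence>
        <xs:element ref="cml:molecule" minOccurs="0" maxOccurs="unbounded"/>
      </xs:sequence>
    </xs:complexType>
  </xs:element>

  <xs:element name="molecule">
    <xs:complexType>
      <xs:attribute name="id" type="xs:ID" use="required"/>
      <xs:attribute name="formula" type="xs:string" use="required"/>
      <xs:attribute name="formalCharge" type="xs:integer"/>
      <!-- ref carries the elemental formula path (EFP) string -->
      <xs:attribute name="ref" type="xs:string" use="required"/>
      <xs:attribute name="parentRef" type="xs:IDREF"/>
    </xs:complexType>
  </xs:element>

  <xs:element name="spectrumList">
    <xs:complexType>
      <xs:sequence>
        <xs:element ref="cml:spectrum" minOccurs="0" maxOccurs="unbounded"/>
      </xs:sequence>
    </xs:complexType>
  </xs:element>

  <xs:element name="spectrum">
    <xs:complexType>
      <xs:sequence>
        <xs:element ref="cml:peakList"/>
      </xs:sequence>
      <xs:attribute name="id" type="xs:ID" use="required"/>
      <xs:attribute name="type" type="xs:string" fixed="massSpectrum"/>
    </xs:complexType>
  </xs:element>

  <xs:element name="peakList">
    <xs:complexType>
      <xs:sequence>
        <xs:element ref="cml:peak" minOccurs="0" maxOccurs="unbounded"/>
      </xs:sequence>
    </xs:complexType>
  </xs:element>

  <xs:element name="peak">
    <xs:complexType>
      <xs:attribute name="moleculeRefs" type="xs:IDREF" use="required"/>
      <xs:attribute name="xValue" type="xs:double"/>
      <xs:attribute name="yValue" type="xs:double" use="required"/>
      <xs:attribute name="xUnits" type="xs:string"/>
      <xs:attribute name="yUnits" type="xs:string"/>
    </xs:complexType>
  </xs:element>

</xs:schema>
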