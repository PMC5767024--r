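<?xml version="1.0" encoding="UTF-8"?>
<!-- Simplified CDA-R2-like template schema for ckdscreen clinical
     documents. Unknown vendor sections are allowed after the known ones
     (lax wildcard), mirroring the opaque-extension contract of the
     parser. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema"
           targetNamespace="urn:ckdscreen:cda:simplified"
           xmlns:c="urn:ckdscreen:cda:simplified"
           elementFormDefault="qualified">

  <xs:element name="ClinicalDocument">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="header" type="c:Header"/>
        <xs:element name="medications" type="c:Medications"/>
        <xs:element name="allergies" type="c:Allergies"/>
        <xs:element name="labResults" type="c:LabResults"/>
        <xs:element name="riskEvaluation" type="c:RiskEvaluation"/>
        <xs:any namespace="##any" processContents="lax" minOccurs="0"
                maxOccurs="unbounded"/>
      </xs:sequence>
    </xs:complexType>
  </xs:element>

  <xs:complexType name="Header">
    <xs:sequence>
      <xs:element name="patient">
        <xs:complexType>
          <xs:sequence>
            <xs:element name="id" type="xs:string"/>
            <xs:element name="gender" type="c:Gender"/>
            <xs:element name="age" type="xs:decimal"/>
            <xs:element name="weight" type="xs:decimal"/>
            <xs:element name="sah" type="xs:boolean"/>
            <xs:element name="dm" type="xs:boolean"/>
          </xs:sequence>
        </xs:complexType>
      </xs:element>
      <xs:element name="author" type="xs:string"/>
      <xs:element name="effectiveTime" type="xs:string"/>
    </xs:sequence>
  </xs:complexType>

  <xs:simpleType name="Gender">
    <xs:restriction base="xs:string">
      <xs:enumeration value="male"/>
      <xs:enumeration value="female"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:complexType name="Medications">
    <xs:sequence>
      <xs:element name="medication" minOccurs="0" maxOccurs="unbounded">
        <xs:complexType>
          <xs:sequence>
            <xs:element name="substance" type="xs:string"/>
            <xs:element name="dose" type="xs:string" minOccurs="0"/>
            <xs:element name="schedule" type="xs:string" minOccurs="0"/>
          </xs:sequence>
        </xs:complexType>
      </xs:element>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="Allergies">
    <xs:sequence>
      <xs:element name="allergy" minOccurs="0" maxOccurs="unbounded">
        <xs:complexType>
          <xs:sequence>
            <xs:element name="substance" type="xs:string"/>
            <xs:element name="reaction" type="xs:string" minOccurs="0"/>
          </xs:sequence>
        </xs:complexType>
      </xs:element>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="LabResults">
    <xs:sequence>
      <xs:element name="result" minOccurs="0" maxOccurs="unbounded">
        <xs:complexType>
          <xs:sequence>
            <xs:element name="name" type="xs:string"/>
            <xs:element name="value" type="xs:decimal"/>
            <xs:element name="unit" type="xs:string"/>
            <xs:element name="date" type="xs:string" minOccurs="0"/>
          </xs:sequence>
        </xs:complexType>
      </xs:element>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="RiskEvaluation">
    <xs:sequence minOccurs="0">
      <xs:element name="proteinuriaCategory" type="xs:string"/>
      <xs:element name="stage" type="xs:string"/>
      <xs:element name="riskLevel" type="xs:string"/>
      <xs:element name="gfr" type="xs:decimal"/>
      <xs:element name="narrative" type="xs:string"/>
      <xs:element name="time" type="xs:string"/>
    </xs:sequence>
  </xs:complexType>

</xs:schema>
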